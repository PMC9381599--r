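# Pluggable registry of base measures. The built-in set covers every
# measure family of the extraction layer (activity, transitions, outings,
# fridge usage, door time-of-day, sleep architecture, bed exits,
# toss-turns, in-bed activity, nocturnal heart rate incl. dipping,
# respiration, spectral band power, cosinor rhythmicity). Users may extend
# it with their own daily extractors.

.dexhaust_registry <- new.env(parent = emptyenv())

measure_def <- function(measure_id, source, granularity, unit, description) {
  tibble(
    measure_id = measure_id, source = source, granularity = granularity,
    unit = unit, description = description
  )
}

default_registry_defs <- function() {
  spectral_block <- function(prefix, channel) {
    bind_rows(
      measure_def(
        paste0(prefix, "_power_", c("low", "mid", "high")), "bed", "nightly", "fraction",
        paste0(
          "Fraction of nocturnal ", channel, " spectral power in the ",
          c("(0, 0.01]", "(0.01, 0.04]", "(0.04, 0.125]"), " Hz band (Welch periodogram)."
        )
      ),
      measure_def(
        paste0(prefix, "_spectral_entropy"), "bed", "nightly", "unitless",
        paste0("Normalized Shannon entropy of the nocturnal ", channel, " spectrum; high values = broadband/irregular.")
      ),
      measure_def(
        paste0(prefix, "_total_power"), "bed", "nightly", "units^2",
        paste0("Total Welch spectral power of the nocturnal ", channel, " channel.")
      )
    )
  }
  bind_rows(
    measure_def(
      "total_activity", "pir", "daily", "min",
      "Total PIR activity summed over all rooms; overall physical/behavioural activity level."
    ),
    measure_def(
      paste0("activity_", room_labels()), "pir", "daily", "min",
      paste0("Active PIR minutes in the ", room_labels(), "; room-specific behaviour (e.g. kitchen ~ meal preparation).")
    ),
    measure_def(
      "room_transition_count", "pir", "daily", "count",
      "Number of changes of the most-recently-active room; in-home mobility."
    ),
    measure_def(
      "activity_fragmentation", "pir", "daily", "1/min",
      "Active/inactive alternations of the union activity signal per active minute; fragmented vs consolidated activity."
    ),
    measure_def(
      "room_entropy", "pir", "daily", "nats",
      "Shannon entropy of activity over the five essential rooms; behavioural complexity/diversity of space use."
    ),
    measure_def(
      "outing_count", "door", "daily", "count",
      "Number of outings detected as entrance-door events bracketing interior PIR silence; out-of-home activity."
    ),
    measure_def(
      "outing_duration_total", "door", "daily", "min",
      "Total daily time spent outside the apartment."
    ),
    measure_def(
      "fridge_use_count", "door", "daily", "count",
      "Fridge-door open events; eating-related behaviour."
    ),
    measure_def(
      paste0("entrance_door_tod_", c("first", "middle", "last")), "door", "daily", "h",
      paste0(c("First", "Median", "Last"), " entrance-door usage time of day; daily routine timing.")
    ),
    measure_def(
      paste0("fridge_door_tod_", c("first", "middle", "last")), "door", "daily", "h",
      paste0(c("First", "Median", "Last"), " fridge usage time of day; meal-timing regularity.")
    ),
    measure_def("sleep_duration", "bed", "nightly", "h", "Hours of non-awake sleep-stage time per night."),
    measure_def("time_in_bed", "bed", "nightly", "h", "Duration of the detected in-bed period."),
    measure_def("sleep_onset_tod", "bed", "nightly", "h", "Clock time of first non-awake stage sample."),
    measure_def("sleep_offset_tod", "bed", "nightly", "h", "Clock time of final awakening."),
    measure_def("sleep_efficiency", "bed", "nightly", "fraction", "Sleep duration over time in bed."),
    measure_def(
      paste0("stage_frac_", c("rem", "deep", "light", "awake")), "bed", "nightly", "fraction",
      paste0("Fraction of non-missing stage samples scored ", c("REM", "deep", "light", "awake"), ".")
    ),
    measure_def("bed_exit_count", "bed", "nightly", "count", "Number of bed-exit events; nocturnal restlessness/toileting."),
    measure_def("toss_turn_count", "bed", "nightly", "count", "Number of toss-and-turn events."),
    measure_def("activity_in_bed", "bed", "nightly", "a.u.", "Mean bed-sensor activity channel; movement intensity in bed."),
    measure_def("waso", "bed", "nightly", "min", "Wake after sleep onset; sleep continuity."),
    measure_def("hr_mean", "bed", "nightly", "bpm", "Mean nocturnal heart rate."),
    measure_def("hr_min", "bed", "nightly", "bpm", "Minimum nocturnal heart rate."),
    measure_def("hr_max", "bed", "nightly", "bpm", "Maximum nocturnal heart rate."),
    measure_def("hr_sd", "bed", "nightly", "bpm", "Nocturnal heart-rate variability (sample SD)."),
    measure_def(
      "hr_dipping", "bed", "nightly", "fraction",
      "Within-night heart-rate dipping: (early-night baseline - minimum 10-min rolling mean) / baseline."
    ),
    measure_def("rr_mean", "bed", "nightly", "breaths/min", "Mean nocturnal respiration rate."),
    measure_def("rr_sd", "bed", "nightly", "breaths/min", "Nocturnal respiration-rate variability."),
    spectral_block("hr", "heart-rate"),
    spectral_block("rr", "respiration-rate"),
    spectral_block("inbed", "in-bed-activity"),
    measure_def(
      c("cosinor_mesor", "cosinor_amplitude", "cosinor_acrophase", "cosinor_rsq"),
      "pir", "per_segment", c("min/10min", "min/10min", "h", "unitless"),
      c(
        "Cosinor rhythm-adjusted mean of bi-weekly PIR activity (10-min bins).",
        "Cosinor amplitude of the 24-h activity rhythm; rhythm strength.",
        "Cosinor acrophase: clock time of the daily activity peak.",
        "Cosinor goodness of fit; rhythm regularity."
      )
    )
  )
}

init_registry <- function() {
  assign("defs", default_registry_defs(), envir = .dexhaust_registry)
  assign("extractors", list(), envir = .dexhaust_registry)
}

#' The base-measure registry
#'
#' Returns the catalogue of registered base measures: every daily, nightly
#' and per-segment measure the extraction layer emits, with its source
#' sensor system, granularity, unit, and a short statement of the
#' hypothesis it encodes.
#'
#' @return Tibble with columns `measure_id`, `source` (`pir`/`door`/`bed`),
#'   `granularity` (`daily`/`nightly`/`per_segment`), `unit`,
#'   `description`.
#' @seealso [register_measure()], [export_registry_json()]
#' @export
measure_registry <- function() {
  if (!exists("defs", envir = .dexhaust_registry)) init_registry()
  get("defs", envir = .dexhaust_registry)
}

#' Register a user-defined base measure
#'
#' Extends the registry with a custom daily measure. The extractor is
#' called once per valid day as `extractor(rec, day)` (a
#' [home_recording()] and one row of [split_days()]) and must return a
#' scalar (or `NA`).
#'
#' @param measure_id Unique snake_case id; registering an existing id is an
#'   error.
#' @param source `"pir"`, `"door"` or `"bed"` (controls which validity rule
#'   gates the day).
#' @param granularity Currently `"daily"` for custom measures.
#' @param unit,description Documentation fields.
#' @param extractor Function `(rec, day) -> numeric(1)`.
#' @return The updated registry tibble, invisibly.
#' @export
register_measure <- function(measure_id, source, granularity = "daily",
                             unit = "", description = "", extractor = NULL) {
  defs <- measure_registry()
  if (measure_id %in% defs$measure_id) {
    abort(sprintf("measure_id '%s' is already registered", measure_id))
  }
  stopifnot(source %in% c("pir", "door", "bed"), granularity %in% c("daily", "nightly", "per_segment"))
  assign("defs", bind_rows(defs, measure_def(measure_id, source, granularity, unit, description)),
    envir = .dexhaust_registry
  )
  if (!is.null(extractor)) {
    ex <- get("extractors", envir = .dexhaust_registry)
    ex[[measure_id]] <- extractor
    assign("extractors", ex, envir = .dexhaust_registry)
  }
  invisible(measure_registry())
}

#' Reset the registry to the built-in measure set
#' @return The default registry tibble, invisibly.
#' @export
reset_measure_registry <- function() {
  init_registry()
  invisible(measure_registry())
}

registry_extractors <- function() {
  if (!exists("extractors", envir = .dexhaust_registry)) init_registry()
  get("extractors", envir = .dexhaust_registry)
}

#' Export the registry as a JSON catalogue
#'
#' @param path Output file.
#' @param registry Registry tibble (default: current registry).
#' @return `path`, invisibly.
#' @export
export_registry_json <- function(path, registry = measure_registry()) {
  jsonlite::write_json(registry, path, pretty = TRUE)
  invisible(path)
}
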