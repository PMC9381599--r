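#' Room labels used by the PIR sensor network
#'
#' The monitoring system places one passive-infrared (PIR) motion sensor in
#' each of the five "essential" rooms of a single-resident apartment, with a
#' catch-all label for any additional sensor.
#'
#' @param essential_only If `TRUE` (default) return only the five essential
#'   rooms; otherwise include `"other"`.
#' @return Character vector of room labels.
#' @export
#' @examples
#' room_labels()
room_labels <- function(essential_only = TRUE) {
  ess <- c("entrance", "bathroom", "bedroom", "livingroom", "kitchen")
  if (essential_only) ess else c(ess, "other")
}

PIR_PERIOD_S <- 2 # PIR epochs: 0.5 Hz
BED_PERIOD_S <- 4 # bed-sensor channels: 0.25 Hz
STAGE_LEVELS <- c("awake", "rem", "deep", "light")
DOOR_LABELS <- c("entrance", "fridge")

#' Assemble and validate a home recording
#'
#' A `home_recording` bundles one participant's full multi-stream sensor
#' record: run-length-encoded PIR activity per room (on the 2-s epoch grid),
#' door open/close events, and per-night bed-sensor records whose uniform
#' channels (heart rate, respiration rate, in-bed activity, sleep stage)
#' live on a shared 4-s grid.
#'
#' @param participant_id Opaque participant identifier.
#' @param pir Tibble with columns `room`, `start`, `end`, `state` (0/1);
#'   each row is a maximal run of identical PIR state. Runs must be
#'   non-overlapping and time-ordered within a room and have durations that
#'   are whole numbers of 2-s epochs. Gaps between runs are interpreted as
#'   sensor outages (no data), not as inactivity.
#' @param doors Tibble with columns `door` (`"entrance"`/`"fridge"`),
#'   `time` (POSIXct) and `state` (`"open"`/`"close"`), time-ordered per door.
#' @param nights Tibble with columns `start`, `end` (POSIXct) and
#'   list-columns `hr`, `rr`, `activity` (numeric, `NA` allowed), `stage`
#'   (character over awake/rem/deep/light, `NA` = missing), `toss_turns`
#'   (POSIXct event times) and `bed_exits` (tibble with `start`, `end`).
#' @param timezone IANA timezone name of the apartment.
#' @return A validated `home_recording` object.
#' @seealso [read_recording()], [simulate_participant()]
#' @export
home_recording <- function(participant_id, pir = empty_pir(), doors = empty_doors(),
                           nights = empty_nights(), timezone = "UTC") {
  rec <- structure(
    list(
      participant_id = as.character(participant_id),
      pir = as_tibble(pir),
      doors = as_tibble(doors),
      nights = as_tibble(nights),
      timezone = timezone
    ),
    class = "home_recording"
  )
  validate_recording(rec)
}

#' @export
print.home_recording <- function(x, ...) {
  cat(sprintf(
    "<home_recording> participant %s (%s)\n  PIR runs: %d across %d rooms\n  door events: %d\n  nights: %d\n",
    x$participant_id, x$timezone, nrow(x$pir),
    length(unique(x$pir$room)), nrow(x$doors), nrow(x$nights)
  ))
  invisible(x)
}

#' @rdname home_recording
#' @export
empty_pir <- function() {
  tibble(
    room = character(), start = as.POSIXct(character()),
    end = as.POSIXct(character()), state = integer()
  )
}

#' @rdname home_recording
#' @export
empty_doors <- function() {
  tibble(door = character(), time = as.POSIXct(character()), state = character())
}

#' @rdname home_recording
#' @export
empty_nights <- function() {
  tibble(
    start = as.POSIXct(character()), end = as.POSIXct(character()),
    hr = list(), rr = list(), activity = list(), stage = list(),
    toss_turns = list(), bed_exits = list()
  )
}

#' Validate a home recording against its stream invariants
#'
#' Checks the 2-s PIR grid, per-room run ordering, the door-event alphabet,
#' the shared 4-s bed grid, bed-exit containment, strict positivity of heart
#' and respiration rates, and night ordering/disjointness.
#'
#' @param rec A `home_recording`.
#' @return `rec`, invisibly, if valid; otherwise an error describing the
#'   first violated invariant.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "home_recording"))
  pir <- rec$pir
  if (nrow(pir) > 0) {
    bad <- setdiff(unique(pir$room), room_labels(essential_only = FALSE))
    if (length(bad) > 0) {
      abort(sprintf("unknown room label(s): %s", paste(bad, collapse = ", ")))
    }
    if (!all(pir$state %in% c(0L, 1L))) abort("PIR state must be 0 or 1")
    dur <- as.numeric(pir$end) - as.numeric(pir$start)
    if (any(dur <= 0)) abort("PIR runs must have positive duration")
    off <- dur %% PIR_PERIOD_S
    if (any(abs(off) > 1e-6 & abs(off - PIR_PERIOD_S) > 1e-6)) {
      abort("PIR run durations must be whole numbers of 2-s epochs (0.5 Hz grid)")
    }
    for (rm in unique(pir$room)) {
      p <- pir[pir$room == rm, ]
      if (is.unsorted(as.numeric(p$start), strictly = TRUE)) {
        abort(sprintf("PIR runs for room '%s' are not strictly time-ordered", rm))
      }
      if (nrow(p) > 1 && any(as.numeric(p$start[-1]) < as.numeric(p$end[-nrow(p)]) - 1e-9)) {
        abort(sprintf("PIR runs for room '%s' overlap", rm))
      }
    }
  }
  doors <- rec$doors
  if (nrow(doors) > 0) {
    if (!all(doors$door %in% DOOR_LABELS)) {
      abort(sprintf(
        "unknown door label(s): %s",
        paste(setdiff(unique(doors$door), DOOR_LABELS), collapse = ", ")
      ))
    }
    if (!all(doors$state %in% c("open", "close"))) abort("door state must be open/close")
    for (d in unique(doors$door)) {
      tt <- doors$time[doors$door == d]
      if (is.unsorted(as.numeric(tt))) {
        abort(sprintf("door events for '%s' are not time-ordered", d))
      }
    }
  }
  nights <- rec$nights
  if (nrow(nights) > 0) {
    if (is.unsorted(as.numeric(nights$start))) abort("nights are not time-ordered")
    if (nrow(nights) > 1 &&
      any(as.numeric(nights$start[-1]) < as.numeric(nights$end[-nrow(nights)]) - 1e-9)) {
      abort("nights overlap")
    }
    for (i in seq_len(nrow(nights))) {
      n_samp <- night_grid_length(nights$start[i], nights$end[i])
      for (ch in c("hr", "rr", "activity", "stage")) {
        v <- nights[[ch]][[i]]
        if (length(v) != n_samp) {
          abort(sprintf(
            "night %d: channel '%s' has %d samples, expected %d on the 4-s grid",
            i, ch, length(v), n_samp
          ))
        }
      }
      for (ch in c("hr", "rr")) {
        v <- nights[[ch]][[i]]
        if (any(v[!is.na(v)] <= 0)) abort(sprintf("night %d: %s must be > 0 where present", i, ch))
      }
      st <- nights$stage[[i]]
      if (!all(st[!is.na(st)] %in% STAGE_LEVELS)) {
        abort(sprintf("night %d: unknown sleep stage label", i))
      }
      be <- nights$bed_exits[[i]]
      if (!is.null(be) && nrow(be) > 0) {
        if (any(as.numeric(be$start) < as.numeric(nights$start[i]) - 1e-9) ||
          any(as.numeric(be$end) > as.numeric(nights$end[i]) + 1e-9)) {
          abort(sprintf("night %d: bed-exit interval outside in-bed window", i))
        }
        o <- order(be$start)
        if (nrow(be) > 1 &&
          any(as.numeric(be$start[o][-1]) < as.numeric(be$end[o][-nrow(be)]) - 1e-9)) {
          abort(sprintf("night %d: bed-exit intervals overlap", i))
        }
      }
    }
  }
  invisible(rec)
}

night_grid_length <- function(start, end) {
  as.integer(round((as.numeric(end) - as.numeric(start)) / BED_PERIOD_S))
}

#' Expand run-length PIR data to per-epoch states
#'
#' Mostly useful for testing and for writing the per-epoch CSV variant; the
#' package computes on the run-length representation directly.
#'
#' @param pir PIR run tibble (see [home_recording()]).
#' @param room Optional single room to expand.
#' @return Tibble with columns `room`, `timestamp`, `state`, one row per 2-s
#'   epoch covered by a run.
#' @export
pir_epochs <- function(pir, room = NULL) {
  if (!is.null(room)) pir <- pir[pir$room == room, ]
  if (nrow(pir) == 0L) {
    return(tibble(room = character(), timestamp = as.POSIXct(character()), state = integer()))
  }
  n_ep <- as.integer(round((as.numeric(pir$end) - as.numeric(pir$start)) / PIR_PERIOD_S))
  tibble(
    room = rep(pir$room, n_ep),
    timestamp = as.POSIXct(
      unlist(lapply(seq_len(nrow(pir)), function(i) {
        as.numeric(pir$start[i]) + PIR_PERIOD_S * (seq_len(n_ep[i]) - 1L)
      })),
      origin = "1970-01-01", tz = attr(pir$start, "tzone") %||% "UTC"
    ),
    state = rep(pir$state, n_ep)
  )
}

# Collapse per-epoch states back to maximal runs (inverse of pir_epochs for
# gap-free streams).
epochs_to_runs <- function(epochs) {
  if (nrow(epochs) == 0L) return(empty_pir())
  out <- lapply(split(epochs, epochs$room), function(e) {
    e <- e[order(e$timestamp), ]
    t <- as.numeric(e$timestamp)
    new_run <- c(TRUE, diff(t) != PIR_PERIOD_S | diff(e$state) != 0)
    grp <- cumsum(new_run)
    tibble(
      room = e$room[1],
      start = e$timestamp[!duplicated(grp)],
      end = e$timestamp[rev(!duplicated(rev(grp)))] + PIR_PERIOD_S,
      state = as.integer(e$state[!duplicated(grp)])
    )
  })
  arrange(bind_rows(out), .data$room, .data$start)
}

# Span of a recording: earliest and latest observation across streams.
recording_span <- function(rec) {
  ts <- c(
    as.numeric(rec$pir$start), as.numeric(rec$pir$end),
    as.numeric(rec$doors$time),
    as.numeric(rec$nights$start), as.numeric(rec$nights$end)
  )
  if (length(ts) == 0L) return(NULL)
  as.POSIXct(range(ts), origin = "1970-01-01", tz = rec$timezone)
}
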