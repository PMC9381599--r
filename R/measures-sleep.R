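#' Nightly sleep-architecture measures
#'
#' Computes the sleep family of base measures from one anchored main night:
#' total `sleep_duration` (hours of non-awake stage time), `time_in_bed`
#' (hours), onset/offset clock times (decimal hours), `sleep_efficiency`,
#' the four stage fractions over non-missing samples, `bed_exit_count`,
#' `toss_turn_count`, mean `activity_in_bed`, and `waso` (awake minutes
#' between sleep onset and final awakening).
#'
#' @param night One row of the `nights` tibble of a [home_recording()].
#' @param valid Whether the day is valid for the bed system; `FALSE` yields
#'   all-`NA`.
#' @param tz Timezone for clock-time conversion.
#' @return Named list, `measure_id -> value`.
#' @export
nightly_sleep_measures <- function(night, valid = TRUE, tz = "UTC") {
  ids <- c(
    "sleep_duration", "time_in_bed", "sleep_onset_tod", "sleep_offset_tod",
    "sleep_efficiency", "stage_frac_rem", "stage_frac_deep",
    "stage_frac_light", "stage_frac_awake", "bed_exit_count",
    "toss_turn_count", "activity_in_bed", "waso"
  )
  if (!isTRUE(valid)) {
    return(setNames(as.list(rep(NA_real_, length(ids))), ids))
  }
  start <- night$start[[1]]
  end <- night$end[[1]]
  st <- night$stage[[1]]
  tib <- (as.numeric(end) - as.numeric(start)) / 3600
  out <- setNames(as.list(rep(NA_real_, length(ids))), ids)
  out$time_in_bed <- tib
  out$bed_exit_count <- as.numeric(nrow(night$bed_exits[[1]]))
  out$toss_turn_count <- as.numeric(length(night$toss_turns[[1]]))
  act <- night$activity[[1]]
  out$activity_in_bed <- if (any(!is.na(act))) mean(act, na.rm = TRUE) else NA_real_
  present <- !is.na(st)
  if (any(present)) {
    asleep <- present & st != "awake"
    out$sleep_duration <- sum(asleep) * BED_PERIOD_S / 3600
    for (lv in c("rem", "deep", "light", "awake")) {
      out[[paste0("stage_frac_", lv)]] <- sum(st[present] == lv) / sum(present)
    }
    if (any(asleep)) {
      onset_i <- which(asleep)[1]
      offset_i <- max(which(asleep))
      onset_t <- start + (onset_i - 1L) * BED_PERIOD_S
      offset_t <- start + offset_i * BED_PERIOD_S
      out$sleep_onset_tod <- tod_hours(lubridate::with_tz(onset_t, tz))
      out$sleep_offset_tod <- tod_hours(lubridate::with_tz(offset_t, tz))
      mid <- st[onset_i:offset_i]
      out$waso <- sum(!is.na(mid) & mid == "awake") * BED_PERIOD_S / 60
    }
    out$sleep_efficiency <- if (tib > 0) out$sleep_duration / tib else NA_real_
  }
  out
}

#' Nightly cardiorespiratory measures
#'
#' Heart-rate summaries (`hr_mean`, `hr_min`, `hr_max`, `hr_sd`), the
#' within-night dipping index, and respiration summaries (`rr_mean`,
#' `rr_sd`), all in source units (beats/min, breaths/min).
#'
#' Because the bed sensor records no daytime heart rate, classical
#' day/night dipping is not computable; the package uses a within-night
#' proxy: `hr_dipping = (B - T)/B` where `B` is the mean heart rate over
#' the first `baseline_min` minutes in bed and `T` the minimum
#' `rolling_min`-minute rolling mean across the night.
#'
#' @param night One row of the `nights` tibble.
#' @param valid Whether the day is valid for the bed system.
#' @param min_coverage_min Minimum non-missing heart-rate coverage
#'   (minutes); below it all cardio measures are `NA`.
#' @param baseline_min,rolling_min Dipping-index windows, minutes.
#' @return Named list, `measure_id -> value`.
#' @export
nightly_cardio_measures <- function(night, valid = TRUE, min_coverage_min = 30,
                                    baseline_min = 30, rolling_min = 10) {
  ids <- c("hr_mean", "hr_min", "hr_max", "hr_sd", "hr_dipping", "rr_mean", "rr_sd")
  out <- setNames(as.list(rep(NA_real_, length(ids))), ids)
  if (!isTRUE(valid)) return(out)
  hr <- night$hr[[1]]
  rr <- night$rr[[1]]
  n_ok <- sum(!is.na(hr))
  if (n_ok * BED_PERIOD_S / 60 < min_coverage_min) return(out)
  out$hr_mean <- mean(hr, na.rm = TRUE)
  out$hr_min <- min(hr, na.rm = TRUE)
  out$hr_max <- max(hr, na.rm = TRUE)
  out$hr_sd <- sd(hr, na.rm = TRUE)
  base_n <- as.integer(baseline_min * 60 / BED_PERIOD_S)
  b <- mean(head(hr, base_n), na.rm = TRUE)
  roll <- rolling_mean_na(hr, as.integer(rolling_min * 60 / BED_PERIOD_S))
  t_min <- suppressWarnings(min(roll, na.rm = TRUE))
  if (is.finite(b) && is.finite(t_min) && b > 0) {
    out$hr_dipping <- (b - t_min) / b
  }
  if (any(!is.na(rr))) {
    out$rr_mean <- mean(rr, na.rm = TRUE)
    out$rr_sd <- sd(rr, na.rm = TRUE)
  }
  out
}
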