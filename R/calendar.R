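#' Tile a recording into local calendar days
#'
#' Day windows run from local midnight to the next local midnight
#' (half-open, `[start, end)`), so days crossing a daylight-saving shift are
#' 23 or 25 hours long. Windows cover the closed span from the first to the
#' last observation of any stream.
#'
#' @param rec A [home_recording()].
#' @return Tibble with columns `date`, `start`, `end`; empty for an empty
#'   recording.
#' @export
split_days <- function(rec) {
  span <- recording_span(rec)
  if (is.null(span)) {
    return(tibble(date = as.Date(character()), start = as.POSIXct(character()), end = as.POSIXct(character())))
  }
  d0 <- as.Date(format(span[1], "%Y-%m-%d", tz = rec$timezone))
  d1 <- as.Date(format(span[2], "%Y-%m-%d", tz = rec$timezone))
  dates <- seq(d0, d1, by = "day")
  bounds <- as.POSIXct(paste(c(dates, d1 + 1), "00:00:00"), tz = rec$timezone)
  tibble(date = dates, start = bounds[-length(bounds)], end = bounds[-1])
}

#' Anchor nights to calendar dates (noon-to-noon)
#'
#' Each night is assigned to the local calendar date of the evening it
#' belongs to: the in-bed start's own date when it begins after local noon,
#' else the previous date. When several nights share one anchor date, the
#' longest is kept as the date's main night and the others are flagged as
#' naps (excluded from nightly measures).
#'
#' @param rec A [home_recording()].
#' @return Tibble with one row per night: `date` (anchor), `night_row` (row
#'   index into `rec$nights`), `is_nap`.
#' @export
assign_nights <- function(rec) {
  nights <- rec$nights
  if (nrow(nights) == 0L) {
    return(tibble(date = as.Date(character()), night_row = integer(), is_nap = logical()))
  }
  validate_recording(rec) # overlap of nights is a validation error
  start_date <- as.Date(format(nights$start, "%Y-%m-%d", tz = rec$timezone))
  anchor <- dplyr::if_else(tod_hours(lubridate::with_tz(nights$start, rec$timezone)) >= 12,
    start_date, start_date - 1
  )
  dur <- as.numeric(nights$end) - as.numeric(nights$start)
  out <- tibble(date = anchor, night_row = seq_len(nrow(nights)), dur = dur)
  out <- out |>
    group_by(.data$date) |>
    mutate(is_nap = rank(-.data$dur, ties.method = "first") > 1L) |>
    ungroup() |>
    select(-"dur")
  arrange(out, .data$date, .data$night_row)
}

#' Decide whether a day's data are usable for a sensor system
#'
#' Default inclusion criteria (configurable): the PIR/door system is valid
#' when the union of the rooms' reporting epochs covers at least
#' `min_pir_coverage_h` hours of the window and at least one on/off state
#' change occurred; the bed system is valid when the day has an anchored
#' main night with at least `min_stage_h` hours of non-missing sleep-stage
#' samples.
#'
#' @param rec A [home_recording()].
#' @param day One row of [split_days()] (or a list with `start`, `end`,
#'   `date`).
#' @param system `"pir_door"` or `"bed"`.
#' @param min_pir_coverage_h,min_stage_h Validity thresholds in hours.
#' @return Single logical.
#' @export
day_validity <- function(rec, day, system = c("pir_door", "bed"),
                         min_pir_coverage_h = 20, min_stage_h = 3) {
  system <- match.arg(system)
  if (system == "pir_door") {
    pir <- clip_intervals(rec$pir, day$start, day$end)
    if (nrow(pir) == 0L) return(FALSE)
    u <- merge_intervals(pir$start, pir$end)
    coverage_h <- sum(as.numeric(u$end) - as.numeric(u$start)) / 3600
    has_change <- length(unique(pir$state)) > 1L
    coverage_h >= min_pir_coverage_h && has_change
  } else {
    an <- assign_nights(rec)
    main <- an[an$date == day$date & !an$is_nap, ]
    if (nrow(main) == 0L) return(FALSE)
    st <- rec$nights$stage[[main$night_row[1]]]
    sum(!is.na(st)) * BED_PERIOD_S / 3600 >= min_stage_h
  }
}
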