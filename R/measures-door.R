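#' Daily door-usage measures
#'
#' Computes the outing/fridge family of base measures for one calendar day:
#' `outing_count` and `outing_duration_total` (minutes), `fridge_use_count`
#' (open events) and the time-of-day measures
#' `entrance_door_tod_first/middle/last` and
#' `fridge_door_tod_first/middle/last` in decimal hours (middle = median
#' open-event time).
#'
#' Outing detection: a pair of consecutive entrance-door events with zero
#' PIR activity in every room in between marks an outing spanning the quiet
#' gap; gaps shorter than `min_outing_min` minutes are treated as
#' door-answering artifacts and ignored.
#'
#' @param doors Door-event tibble of a [home_recording()].
#' @param pir PIR run tibble (used to establish interior silence).
#' @param day One row of [split_days()].
#' @param valid Whether the day is valid for the PIR/door system.
#' @param min_outing_min Minimum quiet gap, minutes (default 5).
#' @param tz Timezone for time-of-day conversion.
#' @return Named list, `measure_id -> value` (`NA` = missing).
#' @export
daily_door_measures <- function(doors, pir, day, valid = TRUE, min_outing_min = 5,
                                tz = "UTC") {
  ids <- c(
    "outing_count", "outing_duration_total", "fridge_use_count",
    paste0("entrance_door_tod_", c("first", "middle", "last")),
    paste0("fridge_door_tod_", c("first", "middle", "last"))
  )
  if (!isTRUE(valid)) {
    return(setNames(as.list(rep(NA_real_, length(ids))), ids))
  }
  ev <- doors[as.numeric(doors$time) >= as.numeric(day$start) &
    as.numeric(doors$time) < as.numeric(day$end), , drop = FALSE]
  act <- pir[pir$state == 1L, , drop = FALSE]
  act <- clip_intervals(act, day$start, day$end)

  tods <- function(door_name) {
    t <- ev$time[ev$door == door_name & ev$state == "open"]
    if (length(t) == 0L) {
      return(c(first = NA_real_, middle = NA_real_, last = NA_real_))
    }
    h <- tod_hours(lubridate::with_tz(t, tz))
    c(first = min(h), middle = median(h), last = max(h))
  }
  ent <- tods("entrance")
  fri <- tods("fridge")

  entrance_ev <- ev[ev$door == "entrance", , drop = FALSE]
  outing_count <- 0L
  outing_total <- 0
  if (nrow(entrance_ev) >= 2) {
    t <- sort(as.numeric(entrance_ev$time))
    for (i in seq_len(length(t) - 1L)) {
      gap <- t[i + 1L] - t[i]
      if (gap < min_outing_min * 60) next
      interior <- overlap_seconds(act$start, act$end, t[i], t[i + 1L])
      if (interior == 0) {
        outing_count <- outing_count + 1L
        outing_total <- outing_total + gap / 60
      }
    }
  }
  list(
    outing_count = as.numeric(outing_count),
    outing_duration_total = outing_total,
    fridge_use_count = as.numeric(sum(ev$door == "fridge" & ev$state == "open")),
    entrance_door_tod_first = ent[["first"]],
    entrance_door_tod_middle = ent[["middle"]],
    entrance_door_tod_last = ent[["last"]],
    fridge_door_tod_first = fri[["first"]],
    fridge_door_tod_middle = fri[["middle"]],
    fridge_door_tod_last = fri[["last"]]
  )
}
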