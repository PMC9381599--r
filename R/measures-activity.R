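#' Daily PIR activity measures
#'
#' Computes the room-activity family of base measures for one calendar day:
#'
#' * `total_activity` — active epochs summed over all rooms, in minutes;
#' * `activity_<room>` — active minutes in each of the five essential rooms;
#' * `room_transition_count` — number of times the most-recently-active room
#'   changes;
#' * `activity_fragmentation` — active/inactive alternations of the
#'   all-rooms union activity signal, divided by total active minutes of the
#'   union (0 when a single bout spans the day);
#' * `room_entropy` — Shannon entropy (natural log) of the distribution of
#'   active epochs over the five essential rooms, in `[0, ln 5]`.
#'
#' @param pir PIR run tibble of a [home_recording()].
#' @param day One row of [split_days()].
#' @param valid Whether the day passed [day_validity()] for the PIR/door
#'   system; if `FALSE` all values are `NA`.
#' @return Named list, `measure_id -> value` (`NA` = missing).
#' @export
daily_activity_measures <- function(pir, day, valid = TRUE) {
  ids <- c(
    "total_activity", paste0("activity_", room_labels()),
    "room_transition_count", "activity_fragmentation", "room_entropy"
  )
  if (!isTRUE(valid)) {
    return(setNames(as.list(rep(NA_real_, length(ids))), ids))
  }
  runs <- clip_intervals(pir, day$start, day$end)
  act <- runs[runs$state == 1L, , drop = FALSE]
  per_room_min <- vapply(room_labels(), function(rm) {
    a <- act[act$room == rm, , drop = FALSE]
    sum(as.numeric(a$end) - as.numeric(a$start)) / 60
  }, numeric(1))
  total_min <- sum(as.numeric(act$end) - as.numeric(act$start)) / 60

  # transitions of the most-recently-active room
  transitions <- 0L
  if (nrow(act) > 1) {
    seq_rooms <- act$room[order(act$start, act$room)]
    transitions <- sum(seq_rooms[-1] != seq_rooms[-length(seq_rooms)])
  }

  # union bouts and their internal alternation edges
  frag <- NA_real_
  if (nrow(act) > 0) {
    u <- merge_intervals(act$start, act$end)
    onsets <- sum(as.numeric(u$start) > as.numeric(day$start) + 1e-9)
    offsets <- sum(as.numeric(u$end) < as.numeric(day$end) - 1e-9)
    union_min <- sum(as.numeric(u$end) - as.numeric(u$start)) / 60
    frag <- if (union_min > 0) (onsets + offsets) / union_min else NA_real_
  }

  ent <- NA_real_
  if (sum(per_room_min) > 0) {
    p <- per_room_min / sum(per_room_min)
    p <- p[p > 0]
    ent <- -sum(p * log(p))
  }
  out <- c(
    list(total_activity = total_min),
    as.list(setNames(per_room_min, paste0("activity_", room_labels()))),
    list(
      room_transition_count = as.numeric(transitions),
      activity_fragmentation = frag,
      room_entropy = ent
    )
  )
  out
}
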