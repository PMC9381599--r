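#' Extract the daily/nightly base-measure table from a recording
#'
#' Runs every registered daily and nightly extractor over a recording:
#' days are tiled at local midnight, nights are anchored noon-to-noon to
#' the evening's date (naps excluded), per-day validity is established for
#' each sensor system, and invalid days yield explicit `NA` values —
#' missingness is first-class and never imputed here.
#'
#' @param rec A [home_recording()].
#' @param registry Registry tibble (see [measure_registry()]).
#' @param min_pir_coverage_h,min_stage_h Day-validity thresholds (hours),
#'   see [day_validity()].
#' @param min_outing_min Outing quiet-gap threshold (minutes).
#' @return Long tibble `participant_id, date, measure_id, value` with one
#'   row per (day, daily/nightly registry measure).
#' @seealso [segment_biweekly()], [build_exhaust()], [digital_exhaust()]
#' @export
extract_daily_measures <- function(rec, registry = measure_registry(),
                                   min_pir_coverage_h = 20, min_stage_h = 3,
                                   min_outing_min = 5) {
  days <- split_days(rec)
  empty <- tibble(
    participant_id = character(), date = as.Date(character()),
    measure_id = character(), value = numeric()
  )
  if (nrow(days) == 0L) return(empty)
  tz <- rec$timezone
  an <- assign_nights(rec)
  mains <- an[!an$is_nap, , drop = FALSE]
  custom <- registry_extractors()
  reg_daily <- registry[registry$granularity %in% c("daily", "nightly"), , drop = FALSE]
  spec_channels <- list(hr = "hr", rr = "rr", inbed = "activity")

  pir_by_day <- split_runs_by_day(rec$pir, days)
  door_day <- findInterval(as.numeric(rec$doors$time), as.numeric(days$start))

  rows <- vector("list", nrow(days))
  for (i in seq_len(nrow(days))) {
    day <- days[i, ]
    day_pir <- pir_by_day[[i]]
    day_doors <- rec$doors[door_day == i, , drop = FALSE]
    pir_valid <- pir_day_valid(day_pir, day, min_pir_coverage_h)
    main_row <- mains$night_row[mains$date == day$date]
    night <- if (length(main_row) > 0) rec$nights[main_row[1], ] else NULL
    bed_valid <- !is.null(night) &&
      sum(!is.na(night$stage[[1]])) * BED_PERIOD_S / 3600 >= min_stage_h

    vals <- c(
      daily_activity_measures(day_pir, day, valid = pir_valid),
      daily_door_measures(day_doors, day_pir, day,
        valid = pir_valid,
        min_outing_min = min_outing_min, tz = tz
      ),
      nightly_sleep_measures(night %||% empty_nights()[0, ], valid = bed_valid && !is.null(night), tz = tz),
      nightly_cardio_measures(night %||% empty_nights()[0, ], valid = bed_valid && !is.null(night))
    )
    for (pref in names(spec_channels)) {
      ch <- if (bed_valid) night[[spec_channels[[pref]]]][[1]] else numeric(0)
      sp <- spectral_measures(ch)
      names(sp) <- paste0(pref, "_", names(sp))
      vals <- c(vals, sp)
    }
    for (mid in names(custom)) {
      def <- registry[registry$measure_id == mid, ]
      ok <- if (def$source[1] == "bed") bed_valid else pir_valid
      vals[[mid]] <- if (ok) as.numeric(custom[[mid]](rec, day)) else NA_real_
    }
    keep <- intersect(names(vals), reg_daily$measure_id)
    rows[[i]] <- tibble(
      participant_id = rec$participant_id, date = day$date,
      measure_id = keep, value = as.numeric(unlist(vals[keep], use.names = FALSE))
    )
  }
  bind_rows(rows)
}

# Pre-split PIR runs at local-midnight boundaries and bucket them per day
# window; start/end become numeric seconds (the measure extractors only do
# interval arithmetic on them). Returns a list with one data frame per day.
split_runs_by_day <- function(pir, days) {
  n_days <- nrow(days)
  bounds <- as.numeric(days$start)
  end_last <- as.numeric(days$end[n_days])
  room <- pir$room
  s <- as.numeric(pir$start)
  e <- as.numeric(pir$end)
  state <- pir$state
  # split runs that cross one or more midnights
  i0 <- findInterval(s, bounds)
  i1 <- findInterval(pmax(e - 1e-9, s), bounds)
  cross <- which(i1 > i0)
  if (length(cross) > 0) {
    extra_room <- character(0)
    extra_s <- extra_e <- numeric(0)
    extra_state <- integer(0)
    for (j in cross) {
      cuts <- c(s[j], bounds[(i0[j] + 1):i1[j]], e[j])
      k <- length(cuts) - 1L
      extra_room <- c(extra_room, rep(room[j], k))
      extra_s <- c(extra_s, cuts[-length(cuts)])
      extra_e <- c(extra_e, cuts[-1])
      extra_state <- c(extra_state, rep(state[j], k))
    }
    room <- c(room[-cross], extra_room)
    s <- c(s[-cross], extra_s)
    e <- c(e[-cross], extra_e)
    state <- c(state[-cross], extra_state)
  }
  idx <- findInterval(s, bounds)
  keep <- idx >= 1L & idx <= n_days & e > s
  df <- data.frame(room = room[keep], start = s[keep], end = e[keep], state = state[keep])
  out <- rep(list(df[0, ]), n_days)
  sp <- split(df, idx[keep])
  out[as.integer(names(sp))] <- sp
  out
}

# Validity of the PIR/door system for one pre-split day.
pir_day_valid <- function(day_pir, day, min_pir_coverage_h) {
  if (nrow(day_pir) == 0L) return(FALSE)
  u <- merge_intervals(day_pir$start, day_pir$end)
  coverage_h <- sum(u$end - u$start) / 3600
  coverage_h >= min_pir_coverage_h && length(unique(day_pir$state)) > 1L
}

# Binned PIR union activity signal over an arbitrary window, for cosinor
# fitting: minutes of union activity per 10-min bin.
pir_activity_signal <- function(rec, start, end, bin_min = 10) {
  act <- rec$pir[rec$pir$state == 1L, , drop = FALSE]
  act <- clip_intervals(act, start, end)
  n_bins <- ceiling(as.numeric(difftime(end, start, units = "mins")) / bin_min)
  if (n_bins <= 0) return(tibble(time = as.POSIXct(character()), value = numeric()))
  bin_start <- as.numeric(start) + (seq_len(n_bins) - 1L) * bin_min * 60
  vals <- numeric(n_bins)
  if (nrow(act) > 0) {
    u <- merge_intervals(act$start, act$end)
    us <- as.numeric(u$start)
    ue <- as.numeric(u$end)
    binw <- bin_min * 60
    t0 <- as.numeric(start)
    for (k in seq_along(us)) { # each union bout spans few bins
      b0 <- max(1L, 1L + floor((us[k] - t0) / binw))
      b1 <- min(n_bins, 1L + floor((ue[k] - 1e-9 - t0) / binw))
      for (b in b0:b1) {
        lo <- t0 + (b - 1L) * binw
        vals[b] <- vals[b] + (min(ue[k], lo + binw) - max(us[k], lo)) / 60
      }
    }
  }
  tibble(
    time = as.POSIXct(bin_start, origin = "1970-01-01", tz = rec$timezone),
    value = vals
  )
}
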