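# Synthetic-cohort generator. Emulates the statistical structure of the
# three sensor streams (room-level PIR at 0.5 Hz, entrance/fridge door
# events, bed-sensor nights at 0.25 Hz) with controllable phenotype
# effects and device outages, so every pipeline stage is testable without
# clinical data.

#' Behavioural routine parameters for the simulator
#'
#' Describes one synthetic resident: sleep timing, room-occupancy dynamics,
#' outing and fridge habits, nocturnal cardiorespiratory baselines, sleep
#' stage dynamics and in-bed movement. All rates are per day or per night.
#'
#' @param sleep_onset_mean,sleep_onset_sd Bedtime, decimal hours (values
#'   above 24 = after midnight).
#' @param sleep_duration_mean,sleep_duration_sd In-bed duration, hours.
#' @param room_dwell_rates Named mean dwell minutes per room; also the
#'   relative odds of entering each room.
#' @param transition_rate Expected number of room changes per day.
#' @param outing_rate Outings per day (Poisson).
#' @param outing_duration_mean Mean outing duration, minutes.
#' @param fridge_rate Fridge-door openings per day (Poisson).
#' @param hr_baseline Early-night heart-rate baseline, beats/min.
#' @param hr_dip_frac,hr_dip_frac_sd Mean and night-to-night SD of the
#'   nocturnal heart-rate dip fraction (truncated to `[0, 1]`).
#' @param rr_baseline Respiration baseline, breaths/min.
#' @param stage_transition_matrix 4x4 row-stochastic matrix over
#'   awake/rem/deep/light governing stage-bout succession.
#' @param toss_turn_rate,bed_exit_rate Events per night (Poisson).
#' @param activity_in_bed_mean Scale of the in-bed activity channel, a.u.
#' @param hr_noise_sd Stationary SD of the AR(1) heart-rate noise.
#' @param ar1 AR(1) coefficient at 4-s steps.
#' @return A validated `routine_params` list.
#' @export
routine_params <- function(sleep_onset_mean = 22.75, sleep_onset_sd = 0.6,
                           sleep_duration_mean = 8, sleep_duration_sd = 0.6,
                           room_dwell_rates = c(
                             livingroom = 45, kitchen = 15, bedroom = 15,
                             bathroom = 6, entrance = 2, other = 10
                           ),
                           transition_rate = 60,
                           outing_rate = 1.5, outing_duration_mean = 90,
                           fridge_rate = 6,
                           hr_baseline = 65, hr_dip_frac = 0.12, hr_dip_frac_sd = 0.04,
                           rr_baseline = 14,
                           stage_transition_matrix = default_stage_matrix(),
                           toss_turn_rate = 12, bed_exit_rate = 1,
                           activity_in_bed_mean = 1,
                           hr_noise_sd = 1, ar1 = 0.9) {
  p <- as.list(environment())
  class(p) <- "routine_params"
  validate_routine(p)
}

default_stage_matrix <- function() {
  m <- rbind(
    awake = c(0.05, 0.10, 0.05, 0.80),
    rem = c(0.15, 0.05, 0.10, 0.70),
    deep = c(0.10, 0.10, 0.05, 0.75),
    light = c(0.15, 0.25, 0.30, 0.30)
  )
  colnames(m) <- STAGE_LEVELS
  m
}

validate_routine <- function(p) {
  rates <- c(
    p$transition_rate, p$outing_rate, p$outing_duration_mean, p$fridge_rate,
    p$toss_turn_rate, p$bed_exit_rate, p$activity_in_bed_mean,
    p$room_dwell_rates, p$hr_noise_sd
  )
  if (any(rates < 0)) abort("routine rates must be >= 0")
  if (p$hr_dip_frac < 0 || p$hr_dip_frac > 1) abort("hr_dip_frac must be in [0, 1]")
  m <- p$stage_transition_matrix
  if (!is.matrix(m) || any(dim(m) != 4) || any(abs(rowSums(m) - 1) > 1e-9) || any(m < 0)) {
    abort("stage_transition_matrix must be 4x4 row-stochastic")
  }
  if (p$sleep_duration_mean <= 0 || p$hr_baseline <= 0 || p$rr_baseline <= 0) {
    abort("sleep duration and cardio baselines must be positive")
  }
  invisible(p)
}

#' Phenotype specification: latent severities and their routine effects
#'
#' Maps latent per-assessment severities (in `[0, 1]`) to shifts of routine
#' parameters. The default effect table follows the qualitative directions
#' associated with each outcome: frailty lowers fridge use, in-home
#' transitions and outings while lengthening sleep; fall risk raises in-bed
#' activity, toss-turns and bed exits; depression lengthens sleep and cuts
#' outings; cognitive impairment raises the night-to-night variability of
#' heart-rate dipping and the irregularity of sleep timing. Magnitudes are
#' free configuration.
#'
#' @param severities Named numeric vector over
#'   `TUG/POMA/EFS/GDS/MoCA`, each in `[0, 1]` (missing entries = 0).
#' @param effects Tibble with columns `assessment`, `param`,
#'   `type` (`"add"` or `"mul"`), `value`; a `mul` effect scales the
#'   parameter by `1 + value * severity`, an `add` effect adds
#'   `value * severity`.
#' @return A `phenotype_spec` list.
#' @export
phenotype_spec <- function(severities = c(TUG = 0, POMA = 0, EFS = 0, GDS = 0, MoCA = 0),
                           effects = default_phenotype_effects()) {
  full <- setNames(rep(0, length(ASSESSMENTS)), ASSESSMENTS)
  full[names(severities)] <- severities
  if (any(full < 0 | full > 1)) abort("severities must lie in [0, 1]")
  if (any(!is.finite(effects$value))) abort("effect values must be finite")
  structure(list(severities = full, effects = effects), class = "phenotype_spec")
}

ASSESSMENTS <- c("TUG", "POMA", "EFS", "GDS", "MoCA")

#' @rdname phenotype_spec
#' @export
default_phenotype_effects <- function() {
  tribble_ <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    tibble(
      assessment = m[, 1], param = m[, 2], type = m[, 3],
      value = as.numeric(m[, 4])
    )
  }
  tribble_(
    "TUG", "activity_in_bed_mean", "mul", 0.8,
    "TUG", "bed_exit_rate", "add", 2,
    "TUG", "toss_turn_rate", "add", 8,
    "TUG", "transition_rate", "mul", -0.35,
    "TUG", "outing_duration_mean", "mul", -0.4,
    "POMA", "activity_in_bed_mean", "mul", 0.6,
    "POMA", "bed_exit_rate", "add", 1.5,
    "POMA", "transition_rate", "mul", -0.3,
    "POMA", "outing_rate", "mul", -0.3,
    "EFS", "fridge_rate", "mul", -0.5,
    "EFS", "transition_rate", "mul", -0.4,
    "EFS", "sleep_duration_mean", "add", 1.0,
    "EFS", "outing_rate", "mul", -0.5,
    "GDS", "sleep_duration_mean", "add", 1.2,
    "GDS", "outing_rate", "mul", -0.6,
    "GDS", "fridge_rate", "mul", -0.3,
    "GDS", "sleep_onset_sd", "add", 0.4,
    "MoCA", "hr_dip_frac_sd", "add", 0.12,
    "MoCA", "hr_dip_frac", "add", -0.05,
    "MoCA", "transition_rate", "mul", -0.35,
    "MoCA", "outing_rate", "mul", -0.4,
    "MoCA", "sleep_onset_sd", "add", 0.7,
    "MoCA", "toss_turn_rate", "add", 6,
    "MoCA", "activity_in_bed_mean", "mul", 0.5
  )
}

#' Apply phenotype effects to a routine
#'
#' @param routine A [routine_params()] object.
#' @param phenotype A [phenotype_spec()]; `NULL` leaves the routine
#'   untouched.
#' @return Shifted, re-validated `routine_params`.
#' @export
apply_phenotype <- function(routine, phenotype) {
  if (is.null(phenotype)) return(routine)
  p <- routine
  for (i in seq_len(nrow(phenotype$effects))) {
    e <- phenotype$effects[i, ]
    sev <- phenotype$severities[[e$assessment]]
    if (sev == 0) next
    cur <- p[[e$param]]
    p[[e$param]] <- if (e$type == "mul") cur * (1 + e$value * sev) else cur + e$value * sev
  }
  nonneg <- c(
    "transition_rate", "outing_rate", "outing_duration_mean", "fridge_rate",
    "toss_turn_rate", "bed_exit_rate", "activity_in_bed_mean", "sleep_onset_sd",
    "sleep_duration_sd", "hr_dip_frac_sd"
  )
  for (f in nonneg) p[[f]] <- max(0, p[[f]])
  p$hr_dip_frac <- min(1, max(0, p$hr_dip_frac))
  validate_routine(p)
}

#' Device-outage model
#'
#' @param rate_per_month Outage events per 30 days (Poisson).
#' @param duration_mean_h Mean outage duration, hours (exponential).
#' @param affected_system `"pir_door"`, `"bed"` or `"both"`.
#' @return An `outage_model` list.
#' @export
outage_model <- function(rate_per_month = 0, duration_mean_h = 24,
                         affected_system = c("both", "pir_door", "bed")) {
  affected_system <- match.arg(affected_system)
  if (rate_per_month < 0 || duration_mean_h < 0) abort("outage rate/duration must be >= 0")
  structure(
    list(
      rate_per_month = rate_per_month, duration_mean_h = duration_mean_h,
      affected_system = affected_system
    ),
    class = "outage_model"
  )
}

# Run code under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

snap2 <- function(x) floor(as.numeric(x) / PIR_PERIOD_S) * PIR_PERIOD_S
snap4 <- function(x) floor(as.numeric(x) / BED_PERIOD_S) * BED_PERIOD_S

#' Simulate one participant's home recording
#'
#' Generates `days` days of streams: a semi-Markov room-occupancy process
#' emitting run-length PIR data on the 2-s grid (rooms report an off state
#' whenever no activity occurs, so coverage is complete except during
#' injected outages); entrance and fridge door events consistent with the
#' occupancy (outings are door-event pairs bracketing interior silence, and
#' fridge use pauses while the resident is out); and one night record per
#' day on the 4-s grid, with heart rate following an early-night baseline
#' that dips by a per-night fraction drawn from a truncated normal, AR(1)
#' noise, stage bouts from the stage transition matrix, and Poisson
#' toss-turns and bed exits (bed exits also trigger bathroom PIR activity).
#'
#' @param routine [routine_params()].
#' @param phenotype Optional [phenotype_spec()] shifting the routine.
#' @param days Number of simulated days (>= 1).
#' @param seed Integer seed; identical inputs reproduce identical streams.
#' @param participant_id,timezone,start_date Recording identity.
#' @return A validated [home_recording()] with exactly `days` nights.
#' @export
simulate_participant <- function(routine, phenotype = NULL, days, seed,
                                 participant_id = "sim-1", timezone = "UTC",
                                 start_date = as.Date("2021-03-01")) {
  if (days < 1) abort("days must be >= 1")
  p <- apply_phenotype(routine, phenotype)
  with_local_seed(seed, simulate_participant_impl(p, days, participant_id, timezone, start_date))
}

simulate_participant_impl <- function(p, days, participant_id, timezone, start_date) {
  day0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = timezone)
  day_start <- as.numeric(day0) + 86400 * (seq_len(days + 1L) - 1L)

  # Night schedule: night d belongs to the evening of day d.
  onset_h <- pmin(pmax(rnorm(days, p$sleep_onset_mean, p$sleep_onset_sd), 19), 27.5)
  dur_h <- pmin(pmax(rnorm(days, p$sleep_duration_mean, p$sleep_duration_sd), 4), 11.5)
  night_start <- snap4(day_start[seq_len(days)] + onset_h * 3600)
  night_end <- snap4(night_start + dur_h * 3600)

  rooms <- names(p$room_dwell_rates)
  prob <- p$room_dwell_rates / sum(p$room_dwell_rates)
  mean_dwell_w <- sum(prob * p$room_dwell_rates) # minutes
  act_rooms <- list()
  door_rows <- list()

  for (d in seq_len(days)) {
    wake <- if (d == 1) day_start[1] + 7 * 3600 else night_end[d - 1L]
    awake_len <- night_start[d] - wake
    if (awake_len <= 0) next

    # outings: non-overlapping quiet absences with door events at both ends
    n_out <- rpois(1, p$outing_rate)
    outs <- matrix(numeric(0), ncol = 2)
    if (n_out > 0 && p$outing_duration_mean > 0 && awake_len > 3600) {
      for (k in seq_len(n_out)) {
        dur <- min(max(rexp(1, 1 / p$outing_duration_mean), 10), 240) * 60
        st <- runif(1, wake + 600, night_start[d] - dur - 600)
        if (is.na(st) || st <= wake) next
        if (nrow(outs) == 0 || all(st + dur < outs[, 1] - 300 | st > outs[, 2] + 300)) {
          outs <- rbind(outs, c(st, dur))
        }
      }
    }
    if (nrow(outs) > 0) {
      outs <- outs[order(outs[, 1]), , drop = FALSE]
      for (k in seq_len(nrow(outs))) {
        t_leave <- outs[k, 1]
        t_back <- outs[k, 1] + outs[k, 2]
        door_rows[[length(door_rows) + 1L]] <- tibble(
          door = "entrance",
          time = as.POSIXct(c(t_leave, t_leave + 20, t_back, t_back + 20),
            origin = "1970-01-01", tz = timezone
          ),
          state = c("open", "close", "open", "close")
        )
      }
    }

    # at-home sub-blocks = awake window minus outings
    cuts <- c(wake, t(cbind(outs[, 1], outs[, 1] + outs[, 2])), night_start[d])
    blocks <- matrix(cuts, ncol = 2, byrow = TRUE)
    target_dwell_s <- max(60, awake_len / max(p$transition_rate, 1e-6))
    scale <- (target_dwell_s / 60) / mean_dwell_w

    for (b in seq_len(nrow(blocks))) {
      b0 <- blocks[b, 1]
      b1 <- blocks[b, 2]
      blen <- b1 - b0
      if (blen < 120) next
      # semi-Markov dwells
      m <- ceiling(blen / target_dwell_s * 2) + 5L
      dw_room <- sample(rooms, m, replace = TRUE, prob = prob)
      dw_len <- rexp(m, 1 / (scale * p$room_dwell_rates[dw_room] * 60))
      dw_end <- b0 + cumsum(dw_len)
      keep <- which(dw_end - dw_len < b1)
      dw_room <- dw_room[keep]
      dw_start <- c(b0, head(dw_end[keep], -1))
      # activity bouts within the block (duty cycle ~ 0.4)
      n_cyc <- ceiling(blen / 150 * 1.6) + 5L
      a_len <- rexp(n_cyc, 1 / 60)
      i_len <- rexp(n_cyc, 1 / 90)
      cyc <- as.vector(rbind(a_len, i_len))
      edges <- b0 + cumsum(c(runif(1, 0, 60), cyc))
      a_start <- edges[seq(1, length(edges) - 1L, by = 2)]
      a_end <- edges[seq(2, length(edges), by = 2)]
      ok <- a_start < b1
      a_start <- a_start[ok]
      a_end <- pmin(a_end[ok], b1)
      room_of <- dw_room[pmax(1L, findInterval(a_start, dw_start))]
      for (rm in unique(room_of)) {
        sel <- room_of == rm
        act_rooms[[length(act_rooms) + 1L]] <- tibble(
          room = rm, start = a_start[sel], end = a_end[sel]
        )
      }
    }

    # fridge events while at home
    n_fr <- rpois(1, p$fridge_rate)
    if (n_fr > 0) {
      ft <- sort(runif(n_fr, wake + 60, night_start[d] - 120))
      ft <- ft[c(TRUE, diff(ft) > 60)] # keep open/close pairs disjoint
      if (nrow(outs) > 0) {
        in_out <- vapply(ft, function(t) any(t >= outs[, 1] & t <= outs[, 1] + outs[, 2]), logical(1))
        ft <- ft[!in_out]
      }
      if (length(ft) > 0) {
        door_rows[[length(door_rows) + 1L]] <- tibble(
          door = "fridge",
          time = as.POSIXct(rep(ft, each = 2) + c(0, 30), origin = "1970-01-01", tz = timezone),
          state = rep(c("open", "close"), length(ft))
        )
      }
    }
  }

  nights <- simulate_nights(p, night_start, night_end, timezone)

  # bed exits produce bathroom activity
  for (i in seq_len(nrow(nights))) {
    be <- nights$bed_exits[[i]]
    if (nrow(be) > 0) {
      act_rooms[[length(act_rooms) + 1L]] <- tibble(
        room = "bathroom",
        start = as.numeric(be$start) + 20, end = as.numeric(be$end) - 20
      )
    }
  }

  span <- c(snap2(day_start[1]), snap2(max(night_end)) + PIR_PERIOD_S)
  act <- if (length(act_rooms) > 0) bind_rows(act_rooms) else tibble(room = character(), start = numeric(), end = numeric())
  pir <- activity_to_runs(act, span, room_labels(essential_only = FALSE), timezone)
  doors <- if (length(door_rows) > 0) {
    arrange(bind_rows(door_rows), .data$time, .data$door)
  } else {
    empty_doors()
  }
  home_recording(participant_id, pir = pir, doors = doors, nights = nights, timezone = timezone)
}

# Convert raw active intervals (numeric seconds) into full-coverage
# state-1/state-0 runs on the 2-s grid for every room.
activity_to_runs <- function(act, span, rooms, tz) {
  out <- list()
  for (rm in rooms) {
    a <- act[act$room == rm, , drop = FALSE]
    s <- snap2(a$start)
    e <- snap2(a$end) + PIR_PERIOD_S
    keep <- e > s & e > span[1] & s < span[2]
    s <- pmax(s[keep], span[1])
    e <- pmin(e[keep], span[2])
    if (length(s) > 0) {
      u <- merge_intervals(s, e)
      us <- u$start
      ue <- u$end
    } else {
      us <- numeric(0)
      ue <- numeric(0)
    }
    bounds_s <- c(span[1], ue)
    bounds_e <- c(us, span[2])
    gap <- bounds_e > bounds_s
    runs <- tibble(
      room = rm,
      start = c(bounds_s[gap], us),
      end = c(bounds_e[gap], ue),
      state = rep(c(0L, 1L), c(sum(gap), length(us)))
    )
    out[[rm]] <- runs[order(runs$start), ]
  }
  runs <- bind_rows(out)
  runs$start <- as.POSIXct(runs$start, origin = "1970-01-01", tz = tz)
  runs$end <- as.POSIXct(runs$end, origin = "1970-01-01", tz = tz)
  arrange(runs, .data$room, .data$start)
}

simulate_nights <- function(p, night_start, night_end, tz) {
  rows <- vector("list", length(night_start))
  for (i in seq_along(night_start)) {
    n <- as.integer((night_end[i] - night_start[i]) / BED_PERIOD_S)
    dip <- min(1, max(0, rnorm(1, p$hr_dip_frac, p$hr_dip_frac_sd)))
    # piecewise dip profile: baseline 30 min, ramp 30 min, plateau, recover
    t_min <- (seq_len(n) - 0.5) * BED_PERIOD_S / 60
    total_min <- n * BED_PERIOD_S / 60
    level <- rep(1, n)
    ramp <- t_min > 30 & t_min <= 60
    level[ramp] <- 1 - dip * (t_min[ramp] - 30) / 30
    level[t_min > 60] <- 1 - dip
    rec_zone <- t_min > total_min - 45
    level[rec_zone] <- (1 - dip) + (dip / 2) * (t_min[rec_zone] - (total_min - 45)) / 45
    ar_noise <- function(sd) {
      if (sd <= 0) return(rep(0, n))
      as.numeric(stats::filter(rnorm(n, 0, sd * sqrt(1 - p$ar1^2)), p$ar1, method = "recursive"))
    }
    hr <- pmax(p$hr_baseline * level + ar_noise(p$hr_noise_sd), 25)
    rr <- pmax(p$rr_baseline + ar_noise(0.5), 5)

    stage <- simulate_stages(p$stage_transition_matrix, n)

    # bed exits
    n_be <- rpois(1, p$bed_exit_rate)
    be_s <- numeric(0)
    be_e <- numeric(0)
    if (n_be > 0 && total_min > 120) {
      for (k in seq_len(n_be)) {
        dur <- runif(1, 2, 8) * 60
        st <- snap4(runif(1, night_start[i] + 30 * 60, night_end[i] - 30 * 60 - dur))
        en <- snap4(st + dur)
        if (length(be_s) == 0 || all(en < be_s - 60 | st > be_e + 60)) {
          be_s <- c(be_s, st)
          be_e <- c(be_e, en)
        }
      }
      o <- order(be_s)
      be_s <- be_s[o]
      be_e <- be_e[o]
      for (k in seq_along(be_s)) {
        i0 <- as.integer((be_s[k] - night_start[i]) / BED_PERIOD_S) + 1L
        i1 <- as.integer((be_e[k] - night_start[i]) / BED_PERIOD_S)
        stage[i0:i1] <- "awake"
      }
    }

    n_tt <- rpois(1, p$toss_turn_rate)
    tt <- sort(snap4(runif(n_tt, night_start[i], night_end[i] - BED_PERIOD_S)))
    activity <- abs(rnorm(n, 0, p$activity_in_bed_mean))
    tt_idx <- as.integer((tt - night_start[i]) / BED_PERIOD_S) + 1L
    activity[tt_idx] <- activity[tt_idx] + 3 * max(p$activity_in_bed_mean, 0.5)

    rows[[i]] <- tibble(
      start = as.POSIXct(night_start[i], origin = "1970-01-01", tz = tz),
      end = as.POSIXct(night_end[i], origin = "1970-01-01", tz = tz),
      hr = list(hr), rr = list(rr), activity = list(activity), stage = list(stage),
      toss_turns = list(as.POSIXct(tt, origin = "1970-01-01", tz = tz)),
      bed_exits = list(tibble(
        start = as.POSIXct(be_s, origin = "1970-01-01", tz = tz),
        end = as.POSIXct(be_e, origin = "1970-01-01", tz = tz)
      ))
    )
  }
  bind_rows(rows)
}

# Stage sequence as bouts: successor states drawn from the transition
# matrix, bout dwell times exponential with stage-specific means.
simulate_stages <- function(tm, n) {
  dwell_min <- c(awake = 4, rem = 14, deep = 18, light = 18)
  out <- character(n)
  pos <- 1L
  state <- "awake"
  while (pos <= n) {
    len <- max(1L, as.integer(rexp(1, 1 / dwell_min[state]) * 60 / BED_PERIOD_S))
    out[pos:min(n, pos + len - 1L)] <- state
    pos <- pos + len
    state <- sample(STAGE_LEVELS, 1, prob = tm[state, ])
  }
  out
}

#' Delete stream data over sampled outage intervals
#'
#' Emulates device failures: outage events are drawn as a Poisson process
#' over the recording span with exponential durations, and all data of the
#' affected system falling in an outage interval are removed (PIR runs are
#' cut out, door events dropped, intersecting nights deleted). The input
#' recording is not modified.
#'
#' @param rec A [home_recording()].
#' @param outages An [outage_model()].
#' @param seed Integer seed.
#' @return A new `home_recording`.
#' @export
inject_missingness <- function(rec, outages, seed = 1) {
  if (outages$rate_per_month <= 0) return(rec)
  span <- recording_span(rec)
  span_s <- as.numeric(span)
  months <- (span_s[2] - span_s[1]) / (30 * 86400)
  with_local_seed(seed, {
    n_out <- rpois(1, outages$rate_per_month * months)
    if (n_out == 0) return(rec)
    st <- runif(n_out, span_s[1], span_s[2])
    en <- st + rexp(n_out, 1 / (outages$duration_mean_h * 3600))
    out <- rec
    if (outages$affected_system %in% c("pir_door", "both")) {
      out$pir <- cut_runs(rec$pir, st, en, rec$timezone)
      keep_door <- !vapply(
        as.numeric(rec$doors$time),
        function(t) any(t >= st & t < en), logical(1)
      )
      out$doors <- rec$doors[keep_door, , drop = FALSE]
    }
    if (outages$affected_system %in% c("bed", "both")) {
      ns <- as.numeric(rec$nights$start)
      ne <- as.numeric(rec$nights$end)
      hit <- vapply(seq_along(ns), function(i) any(ns[i] < en & ne[i] > st), logical(1))
      out$nights <- rec$nights[!hit, , drop = FALSE]
    }
    validate_recording(out)
  })
}

# Remove the parts of PIR runs that fall inside cut intervals.
cut_runs <- function(pir, cut_s, cut_e, tz) {
  if (nrow(pir) == 0) return(pir)
  cut_s <- snap2(cut_s)
  cut_e <- snap2(cut_e) + PIR_PERIOD_S
  s <- as.numeric(pir$start)
  e <- as.numeric(pir$end)
  keep <- list()
  for (i in seq_len(nrow(pir))) {
    segs_s <- s[i]
    segs_e <- e[i]
    for (k in seq_along(cut_s)) {
      new_s <- numeric(0)
      new_e <- numeric(0)
      for (j in seq_along(segs_s)) {
        if (cut_e[k] <= segs_s[j] || cut_s[k] >= segs_e[j]) {
          new_s <- c(new_s, segs_s[j])
          new_e <- c(new_e, segs_e[j])
        } else {
          if (cut_s[k] > segs_s[j]) {
            new_s <- c(new_s, segs_s[j])
            new_e <- c(new_e, cut_s[k])
          }
          if (cut_e[k] < segs_e[j]) {
            new_s <- c(new_s, cut_e[k])
            new_e <- c(new_e, segs_e[j])
          }
        }
      }
      segs_s <- new_s
      segs_e <- new_e
      if (length(segs_s) == 0) break
    }
    if (length(segs_s) > 0) {
      keep[[length(keep) + 1L]] <- tibble(
        room = pir$room[i], start = segs_s, end = segs_e, state = pir$state[i]
      )
    }
  }
  if (length(keep) == 0) return(empty_pir())
  out <- bind_rows(keep)
  out$start <- as.POSIXct(out$start, origin = "1970-01-01", tz = tz)
  out$end <- as.POSIXct(out$end, origin = "1970-01-01", tz = tz)
  arrange(out, .data$room, .data$start)
}
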