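# Fixture builders and independent brute-force oracles.

UTC <- "UTC"

ts_utc <- function(x) as.POSIXct(x, tz = UTC)

day_window <- function(date, tz = UTC) {
  d <- as.Date(date)
  tibble::tibble(
    date = d,
    start = as.POSIXct(paste(d, "00:00:00"), tz = tz),
    end = as.POSIXct(paste(d + 1, "00:00:00"), tz = tz)
  )
}

# PIR run covering [start, end) with a state, as a one-row tibble.
pir_run <- function(room, start, end, state) {
  tibble::tibble(room = room, start = ts_utc(start), end = ts_utc(end), state = as.integer(state))
}

# A night on the 4-s grid with constant or supplied channels.
make_night <- function(start, end, hr = 60, rr = 14, activity = 0.5,
                       stage = "light", toss_turns = NULL, bed_exits = NULL) {
  start <- ts_utc(start)
  end <- ts_utc(end)
  n <- as.integer(round(as.numeric(end - start, units = "secs") / 4))
  expand <- function(x) if (length(x) == 1L) rep(x, n) else x
  tibble::tibble(
    start = start, end = end,
    hr = list(expand(hr)), rr = list(expand(rr)),
    activity = list(expand(activity)), stage = list(expand(stage)),
    toss_turns = list(toss_turns %||% as.POSIXct(character(), tz = UTC)),
    bed_exits = list(bed_exits %||% tibble::tibble(
      start = as.POSIXct(character(), tz = UTC),
      end = as.POSIXct(character(), tz = UTC)
    ))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small scripted recording: 3 full days of PIR coverage in all rooms,
# scattered activity, door events and 3 nights.
scripted_recording <- function(id = "t1") {
  rooms <- room_labels()
  cov <- dplyr::bind_rows(lapply(rooms, function(rm) {
    pir_run(rm, "2021-03-01 00:00:00", "2021-03-04 00:00:00", 0)
  }))
  act <- dplyr::bind_rows(
    pir_run("kitchen", "2021-03-01 08:00:00", "2021-03-01 08:30:00", 1),
    pir_run("livingroom", "2021-03-01 10:00:00", "2021-03-01 12:00:00", 1),
    pir_run("kitchen", "2021-03-02 08:00:00", "2021-03-02 08:30:00", 1),
    pir_run("bedroom", "2021-03-02 21:00:00", "2021-03-02 21:30:00", 1),
    pir_run("bathroom", "2021-03-03 07:00:00", "2021-03-03 07:10:00", 1)
  )
  pir <- dplyr::bind_rows(lapply(split(act, act$room), function(a) {
    rm <- a$room[1]
    base <- cov[cov$room == rm, ]
    cut_complement(base, a)
  }))
  pir <- dplyr::bind_rows(pir, cov[!cov$room %in% act$room, ])
  pir <- dplyr::arrange(pir, room, start)
  doors <- tibble::tibble(
    door = c("entrance", "entrance", "fridge", "fridge", "fridge", "fridge"),
    time = ts_utc(c(
      "2021-03-01 09:00:00", "2021-03-01 09:00:40",
      "2021-03-01 07:00:00", "2021-03-01 07:00:30",
      "2021-03-02 12:00:00", "2021-03-02 12:00:30"
    )),
    state = c("open", "close", "open", "close", "open", "close")
  )
  nights <- dplyr::bind_rows(
    make_night("2021-03-01 22:00:00", "2021-03-02 06:00:00"),
    make_night("2021-03-02 22:30:00", "2021-03-03 06:30:00"),
    make_night("2021-03-03 22:00:00", "2021-03-04 00:00:00")
  )
  home_recording(id, pir = pir, doors = doors, nights = nights, timezone = UTC)
}

# Replace the state-0 base run by the complement of the active runs.
cut_complement <- function(base, act) {
  act <- dplyr::arrange(act, start)
  bounds_s <- c(base$start, act$end)
  bounds_e <- c(act$start, base$end)
  keep <- as.numeric(bounds_e) > as.numeric(bounds_s)
  dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(
      room = base$room[1], start = bounds_s[keep], end = bounds_e[keep],
      state = 0L
    ),
    act
  ), start)
}

# ---- brute-force oracles (kept independent of package internals) ----

# quantile by explicit linear interpolation between closest order statistics
bf_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  x[lo] + (h - floor(h)) * (x[hi] - x[lo])
}

bf_sk3 <- function(x) {
  med <- bf_quantile(x, 0.5)
  d <- mean(abs(x - med))
  if (d < 1e-12) {
    return(if (abs(mean(x) - med) < 1e-12) 0 else NA_real_)
  }
  (mean(x) - med) / d
}

bf_kr3 <- function(x, cc = 2.59) {
  n <- length(x)
  s <- sort(x)
  tm <- function(alpha, upper) {
    k <- alpha * n
    v <- if (upper) rev(s) else s
    kf <- floor(k)
    (sum(v[seq_len(kf)]) + if (k > kf) (k - kf) * v[kf + 1] else 0) / k
  }
  (tm(0.05, TRUE) - tm(0.05, FALSE)) / (tm(0.5, TRUE) - tm(0.5, FALSE)) - cc
}

# pairwise (Mann-Whitney) AUC
bf_auc <- function(y, p) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# independent sum-of-mean-absolute SHAP aggregation
bf_global_shap <- function(mats) {
  cols <- colnames(mats[[1]])
  out <- setNames(numeric(length(cols)), cols)
  for (m in mats) {
    for (cn in cols) out[cn] <- out[cn] + mean(abs(m[, cn]))
  }
  out
}

# tiny labelled dataset with a signal feature, built directly (no simulator)
make_tiny_coa_dataset <- function(n_part = 12, n_seg = 3, signal = 2, seed = 99) {
  withr::with_seed(seed, {
    ids <- sprintf("p%02d", seq_len(n_part))
    label <- rep(0:1, length.out = n_part)
    rows <- tidyr::expand_grid(participant_id = ids, segment_index = 0:(n_seg - 1))
    rows$label <- label[match(rows$participant_id, ids)]
    rows$f_signal <- rnorm(nrow(rows), mean = signal * rows$label)
    rows$f_noise1 <- rnorm(nrow(rows))
    rows$f_noise2 <- rnorm(nrow(rows))
    rows$f_bed <- rnorm(nrow(rows), mean = 0.5 * signal * rows$label)
    rows$age <- sample(70:95, nrow(rows), replace = TRUE)
    rows$sex <- rbinom(nrow(rows), 1, 0.5)
    rows$cohort <- rep(1:2, length.out = nrow(rows))
    src <- c(
      f_signal = "pir_door", f_noise1 = "pir_door", f_noise2 = "pir_door",
      f_bed = "bed", age = "demographics", sex = "demographics",
      cohort = "demographics"
    )
    structure(rows,
      feature_cols = names(src), feature_sources = src, assessment = "MoCA",
      class = c("coa_dataset", class(rows))
    )
  })
}
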