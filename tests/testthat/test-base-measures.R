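day1 <- day_window("2021-03-01")

test_that("single-room all-day activity gives degenerate activity measures", {
  pir <- dplyr::bind_rows(
    pir_run("bedroom", "2021-03-01 00:00:00", "2021-03-02 00:00:00", 1),
    lapply(setdiff(room_labels(), "bedroom"), function(rm) {
      pir_run(rm, "2021-03-01 00:00:00", "2021-03-02 00:00:00", 0)
    })
  )
  m <- daily_activity_measures(pir, day1)
  expect_equal(m$total_activity, 1440)
  expect_equal(m$activity_bedroom, 1440)
  expect_equal(m$room_transition_count, 0)
  expect_equal(m$room_entropy, 0)
  expect_equal(m$activity_fragmentation, 0)
})

test_that("uniform activity over the five essential rooms maximises entropy", {
  pir <- dplyr::bind_rows(lapply(seq_along(room_labels()), function(i) {
    rm <- room_labels()[i]
    h0 <- sprintf("2021-03-01 %02d:00:00", 2 * i)
    h1 <- sprintf("2021-03-01 %02d:00:00", 2 * i + 1)
    pir_run(rm, h0, h1, 1)
  }))
  m <- daily_activity_measures(pir, day1)
  expect_equal(m$room_entropy, log(5), tolerance = 1e-12)
})

test_that("room transitions count changes of the most-recently-active room", {
  pir <- dplyr::bind_rows(
    pir_run("kitchen", "2021-03-01 08:00:00", "2021-03-01 08:10:00", 1),
    pir_run("livingroom", "2021-03-01 09:00:00", "2021-03-01 09:30:00", 1),
    pir_run("kitchen", "2021-03-01 10:00:00", "2021-03-01 10:05:00", 1)
  )
  m <- daily_activity_measures(pir, day1)
  expect_equal(m$room_transition_count, 2)
  # three separate union bouts -> 6 internal edges over 45 active minutes
  expect_equal(m$activity_fragmentation, 6 / 45)
})

test_that("invalid days yield missing activity values", {
  m <- daily_activity_measures(empty_pir(), day1, valid = FALSE)
  expect_true(all(is.na(unlist(m))))
})

test_that("outings are quiet gaps between entrance events", {
  doors <- tibble::tibble(
    door = "entrance",
    time = ts_utc(c("2021-03-01 09:00:00", "2021-03-01 11:00:00")),
    state = c("open", "close")
  )
  m <- daily_door_measures(doors, empty_pir(), day1)
  expect_equal(m$outing_count, 1)
  expect_equal(m$outing_duration_total, 120)

  # interior activity in the gap cancels the outing
  pir <- pir_run("kitchen", "2021-03-01 10:00:00", "2021-03-01 10:05:00", 1)
  m2 <- daily_door_measures(doors, pir, day1)
  expect_equal(m2$outing_count, 0)

  # sub-threshold gaps are door answering, not outings
  quick <- tibble::tibble(
    door = "entrance",
    time = ts_utc(c("2021-03-01 09:00:00", "2021-03-01 09:03:00")),
    state = c("open", "close")
  )
  expect_equal(daily_door_measures(quick, empty_pir(), day1)$outing_count, 0)
})

test_that("fridge usage and door time-of-day measures follow the events", {
  doors <- tibble::tibble(
    door = "fridge",
    time = ts_utc(c(
      "2021-03-01 07:00:00", "2021-03-01 07:00:30",
      "2021-03-01 12:00:00", "2021-03-01 12:00:30",
      "2021-03-01 19:00:00", "2021-03-01 19:00:30"
    )),
    state = rep(c("open", "close"), 3)
  )
  m <- daily_door_measures(doors, empty_pir(), day1)
  expect_equal(m$fridge_use_count, 3)
  expect_equal(m$fridge_door_tod_first, 7)
  expect_equal(m$fridge_door_tod_middle, 12)
  expect_equal(m$fridge_door_tod_last, 19)
  expect_true(is.na(m$entrance_door_tod_first))

  none <- daily_door_measures(empty_doors(), empty_pir(), day1)
  expect_equal(none$outing_count, 0)
  expect_equal(none$fridge_use_count, 0)
  expect_true(is.na(none$entrance_door_tod_first))
})

test_that("sleep architecture measures match scripted nights", {
  n8 <- make_night("2021-03-01 22:00:00", "2021-03-02 06:00:00", stage = "light")
  m <- nightly_sleep_measures(n8)
  expect_equal(m$sleep_duration, 8)
  expect_equal(m$time_in_bed, 8)
  expect_equal(m$sleep_efficiency, 1)
  expect_equal(m$stage_frac_light, 1)
  expect_equal(m$waso, 0)
  expect_equal(m$sleep_onset_tod, 22, tolerance = 0.01)

  stages <- rep(c("awake", "rem", "deep", "light"), each = 1800)
  n4 <- make_night("2021-03-01 22:00:00", "2021-03-02 06:00:00", stage = stages)
  m4 <- nightly_sleep_measures(n4)
  expect_equal(
    unlist(m4[c("stage_frac_awake", "stage_frac_rem", "stage_frac_deep", "stage_frac_light")]),
    rep(0.25, 4),
    ignore_attr = TRUE
  )
  expect_equal(
    m4$stage_frac_awake + m4$stage_frac_rem + m4$stage_frac_deep + m4$stage_frac_light,
    1,
    tolerance = 1e-9
  )

  evented <- make_night("2021-03-01 22:00:00", "2021-03-02 06:00:00",
    toss_turns = ts_utc(sprintf("2021-03-02 0%d:00:00", 1:5)),
    bed_exits = tibble::tibble(
      start = ts_utc(c("2021-03-02 02:00:00", "2021-03-02 04:00:00")),
      end = ts_utc(c("2021-03-02 02:05:00", "2021-03-02 04:03:00"))
    )
  )
  me <- nightly_sleep_measures(evented)
  expect_equal(me$bed_exit_count, 2)
  expect_equal(me$toss_turn_count, 5)
})

test_that("cardio measures recover the dipping fraction", {
  flat <- make_night("2021-03-01 22:00:00", "2021-03-02 06:00:00", hr = 60)
  m <- nightly_cardio_measures(flat)
  expect_equal(m$hr_mean, 60)
  expect_equal(m$hr_min, 60)
  expect_equal(m$hr_sd, 0)
  expect_equal(m$hr_dipping, 0)

  n <- 7200 # 8 h at 4 s
  hr <- c(rep(70, 450), rep(56, n - 450))
  dip <- make_night("2021-03-01 22:00:00", "2021-03-02 06:00:00", hr = hr)
  expect_equal(nightly_cardio_measures(dip)$hr_dipping, (70 - 56) / 70, tolerance = 1e-9)

  gone <- make_night("2021-03-01 22:00:00", "2021-03-02 06:00:00", hr = NA_real_)
  expect_true(all(is.na(unlist(nightly_cardio_measures(gone)))))
})

test_that("spectral measures localise tones and spread white noise", {
  fs <- 0.25
  t <- seq(0, by = 1 / fs, length.out = 4096)
  tone <- sin(2 * pi * 0.02 * t)
  m <- spectral_measures(tone, fs = fs)
  expect_gt(m$power_mid, 0.95)
  expect_true(m$power_low >= 0 && m$power_low <= 1)

  withr::with_seed(5, {
    noise <- rnorm(8192)
    mw <- spectral_measures(noise, fs = fs)
    # flat spectrum: band fraction proportional to bandwidth (Nyquist 0.125)
    expect_equal(mw$power_low, 0.01 / 0.125, tolerance = 0.2)
    expect_equal(mw$power_mid, 0.03 / 0.125, tolerance = 0.2)
    expect_equal(mw$power_high, 0.085 / 0.125, tolerance = 0.2)
    expect_gt(mw$spectral_entropy, 0.9)
  })

  flat <- spectral_measures(rep(3, 1000), fs = fs)
  expect_equal(flat$total_power, 0, tolerance = 1e-12)
  expect_true(is.na(flat$spectral_entropy))

  expect_true(all(is.na(unlist(spectral_measures(rnorm(100))))))
})
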