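test_that("simulated streams honour the device grid contracts", {
  rec <- simulate_participant(routine_params(), days = 14, seed = 101)
  expect_equal(nrow(rec$nights), 14)
  expect_silent(validate_recording(rec))
  dur <- as.numeric(rec$pir$end) - as.numeric(rec$pir$start)
  expect_true(all(abs(dur %% 2) < 1e-9 | abs(dur %% 2 - 2) < 1e-9))
  for (i in seq_len(nrow(rec$nights))) {
    n_expect <- as.numeric(rec$nights$end[i] - rec$nights$start[i], units = "secs") / 4
    expect_equal(length(rec$nights$hr[[i]]), n_expect)
    expect_equal(length(rec$nights$stage[[i]]), n_expect)
  }
  expect_error(simulate_participant(routine_params(), days = 0, seed = 1), "days")
  expect_error(routine_params(transition_rate = -1), ">= 0")
})

test_that("identical parameters and seed reproduce identical streams", {
  a <- simulate_participant(routine_params(), days = 6, seed = 77)
  b <- simulate_participant(routine_params(), days = 6, seed = 77)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- simulate_participant(routine_params(), days = 6, seed = 78)
  expect_false(identical(serialize(a, NULL), serialize(c, NULL)))
})

test_that("injected dipping is recovered through the cardio extractor", {
  p <- routine_params(hr_dip_frac = 0.2, hr_dip_frac_sd = 0, hr_noise_sd = 0.05)
  rec <- simulate_participant(p, days = 12, seed = 5)
  daily <- extract_daily_measures(rec)
  dips <- daily$value[daily$measure_id == "hr_dipping"]
  expect_lt(abs(median(dips, na.rm = TRUE) - 0.2), 0.02)
})

test_that("phenotype severity shifts behaviour in the expected directions", {
  vals <- lapply(c(0, 0.5, 1), function(s) {
    rec <- simulate_participant(routine_params(),
      phenotype = phenotype_spec(c(EFS = s)), days = 10, seed = 42
    )
    daily <- extract_daily_measures(rec)
    by_m <- tapply(daily$value, daily$measure_id, mean, na.rm = TRUE)
    by_m[c("fridge_use_count", "room_transition_count", "sleep_duration")]
  })
  fridge <- vapply(vals, `[[`, numeric(1), "fridge_use_count")
  trans <- vapply(vals, `[[`, numeric(1), "room_transition_count")
  sleep <- vapply(vals, `[[`, numeric(1), "sleep_duration")
  expect_true(all(diff(fridge) < 0))
  expect_true(all(diff(trans) < 0))
  expect_true(all(diff(sleep) > 0))
})

test_that("outage injection deletes exactly the affected data", {
  rec <- simulate_participant(routine_params(), days = 14, seed = 8)
  expect_identical(inject_missingness(rec, outage_model(0), seed = 1), rec)

  cut <- inject_missingness(rec, outage_model(4, 36, "bed"), seed = 7)
  expect_lt(nrow(cut$nights), nrow(rec$nights))
  expect_identical(cut$pir, rec$pir)

  # closed loop: enough lost nights push bed derivates below the 10-day floor
  removed <- nrow(rec$nights) - nrow(cut$nights)
  ex <- digital_exhaust(cut)
  if (14 - removed < 10) {
    expect_true(all(is.na(dplyr::select(ex, dplyr::ends_with("_hr_mean")))))
    expect_false(all(is.na(dplyr::select(ex, dplyr::ends_with("_total_activity")))))
  }

  wipe <- inject_missingness(rec, outage_model(100, 24 * 30, "both"), seed = 3)
  daily <- extract_daily_measures(wipe)
  expect_true(all(is.na(daily$value)) || nrow(daily) == 0)

  pristine <- extract_daily_measures(rec)
  full_days <- dplyr::filter(
    pristine,
    date > min(date), date < max(date),
    !startsWith(measure_id, "entrance_door") # no outing on a quiet day is legal
  )
  expect_true(mean(is.na(full_days$value)) < 0.02)
})

test_that("cohort simulation reproduces intended labels and demographics", {
  sim <- simulate_cohort(
    n = 40, case_fraction = c(MoCA = 0.5), days = 2, seed = 202,
    transform = function(rec) NULL
  )
  moca_mean <- sim$assessments |>
    dplyr::filter(assessment == "MoCA") |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(m = mean(score))
  expect_equal(sum(moca_mean$m < 23), 20)
  lab <- dplyr::filter(sim$labels, assessment == "MoCA")
  expect_equal(sum(lab$intended_label), 20)
  expect_equal(nrow(sim$demographics), 40)
  expect_true(all(sim$demographics$age >= 70 & sim$demographics$age <= 100))
  expect_error(simulate_cohort(1, seed = 1), "n must")
  expect_error(simulate_cohort(10, case_fraction = c(MoCA = 1.5), seed = 1), "fraction")
})

test_that("a null cohort shows no phenotype signal in the exhaust", {
  sim <- simulate_cohort(
    n = 20, case_fraction = c(MoCA = 0.5), days = 16, seed = 303,
    effects = null_phenotype_effects(),
    transform = function(rec) digital_exhaust(rec)
  )
  ex <- dplyr::bind_rows(sim$recordings)
  lab <- dplyr::filter(sim$labels, assessment == "MoCA")
  case_ids <- lab$participant_id[lab$intended_label == 1]
  for (m in c("mean_total_activity", "q50_sleep_duration", "mean_hr_dipping")) {
    a <- ex[[m]][ex$participant_id %in% case_ids]
    b <- ex[[m]][!ex$participant_id %in% case_ids]
    expect_gt(suppressWarnings(stats::ks.test(a, b)$p.value), 0.01)
  }
})
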