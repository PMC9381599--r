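test_that("summary statistics match hand/oracle values on canonical cases", {
  s <- summarize_values(c(2, 2, 2, 2))
  expect_equal(s[["mean"]], 2)
  expect_equal(s[["q50"]], 2)
  expect_equal(s[["iqr"]], 0)
  expect_equal(s[["coefvar"]], 0)
  expect_equal(s[["sk3"]], 0)

  s5 <- summarize_values(1:5)
  expect_equal(s5[["q50"]], bf_quantile(1:5, 0.5))
  expect_equal(s5[["iqr"]], bf_quantile(1:5, 0.75) - bf_quantile(1:5, 0.25))
  expect_equal(s5[["mean"]], 3)

  expect_true(all(is.na(summarize_values(numeric(0)))))
  s1 <- summarize_values(7)
  expect_equal(s1[["mean"]], 7)
  expect_equal(s1[["q50"]], 7)
  expect_true(all(is.na(s1[setdiff(names(s1), c("mean", "q50"))])))
  expect_true(is.na(summarize_values(c(0, 0, 0))[["coefvar"]])) # zero mean
})

test_that("summarize is permutation invariant and ignores missing entries", {
  withr::with_seed(31, {
    for (i in 1:50) {
      x <- rnorm(sample(2:14, 1))
      x[sample(length(x), sample(0:(length(x) - 2), 1))] <- NA
      expect_equal(summarize_values(x), summarize_values(sample(x)))
      expect_equal(summarize_values(x), summarize_values(c(x, NA, NA)))
    }
  })
})

test_that("sk3 matches direct formula evaluation and its invariances", {
  expect_equal(robust_skew_sk3(c(0, 0, 0, 10)), 1) # mean 2.5, med 0, mad0 2.5
  expect_equal(robust_skew_sk3(1:5), 0, tolerance = 1e-12)
  withr::with_seed(8, {
    x <- rexp(50)
    expect_equal(robust_skew_sk3(x), bf_sk3(x), tolerance = 1e-12)
    expect_equal(robust_skew_sk3(10 * x), robust_skew_sk3(x), tolerance = 1e-12) # scale-free
    expect_equal(robust_skew_sk3(-x), -robust_skew_sk3(x), tolerance = 1e-12) # sign flip
    big <- rnorm(1e5)
    expect_lt(abs(robust_skew_sk3(big)), 0.02)
  })
  expect_true(is.na(robust_skew_sk3(c(1, 2))))
})

test_that("kr3 is calibrated on the normal and orders tail weight", {
  withr::with_seed(9, {
    z <- rnorm(1e5)
    expect_lt(abs(robust_kurt_kr3(z)), 0.05)
    u <- runif(1e5)
    expect_lt(robust_kurt_kr3(u), robust_kurt_kr3(z)) # light tails
    expect_equal(robust_kurt_kr3(z), bf_kr3(z), tolerance = 1e-12)
    expect_equal(robust_kurt_kr3(3 + 2 * z), robust_kurt_kr3(z), tolerance = 1e-12)
  })
  expect_true(is.na(robust_kurt_kr3(rnorm(10))))
})

make_daily <- function(n_days, measures = "m1", id = "p1", value = 1) {
  tidyr::expand_grid(
    participant_id = id,
    date = as.Date("2021-03-01") + 0:(n_days - 1),
    measure_id = measures
  ) |> dplyr::mutate(value = value)
}

test_that("bi-weekly segmentation is recording-relative and drops partials", {
  expect_equal(nrow(segment_biweekly(make_daily(70))), 5)
  s30 <- segment_biweekly(make_daily(30))
  expect_equal(nrow(s30), 2)
  expect_equal(nrow(segment_biweekly(make_daily(13))), 0)
  expect_equal(s30$segment_index, 0:1)
  expect_equal(s30$start_date, as.Date(c("2021-03-01", "2021-03-15")))
  expect_equal(s30$valid_day_count[[1]][["m1"]], 14L)
})

test_that("the 10-day floor gates derivates and the key set is fixed", {
  reg <- measure_registry()[measure_registry()$measure_id %in%
    c("total_activity", "hr_mean", "fridge_use_count"), ]
  daily <- make_daily(14, measures = c("total_activity", "hr_mean", "fridge_use_count"),
    value = rnorm(42)
  )
  # hr_mean present only 9 days; total_activity exactly 10
  daily$value[daily$measure_id == "hr_mean"][1:5] <- NA
  daily$value[daily$measure_id == "total_activity"][1:4] <- NA
  ex <- build_exhaust(segment_biweekly(daily), registry = reg)
  expect_true(all(is.na(dplyr::select(ex, dplyr::ends_with("_hr_mean")))))
  # kr3 needs >= 20 values and is structurally NA on 14-day segments
  fr <- dplyr::select(ex, dplyr::ends_with("_fridge_use_count"), -dplyr::starts_with("kr3"))
  expect_false(any(is.na(fr)))
  ta <- dplyr::select(ex, dplyr::ends_with("_total_activity"), -dplyr::starts_with("kr3"))
  expect_false(any(is.na(ta)))
  # 3 base measures x 10 stats (+ id columns); no per-segment measures here
  expect_equal(ncol(ex), 2 + 30)
  expect_equal(
    sort(setdiff(names(ex), c("participant_id", "segment_index"))),
    sort(names(feature_sources(ex)))
  )
})

test_that("reducing valid days never resurrects a missing derivate", {
  withr::with_seed(17, {
    reg <- measure_registry()[measure_registry()$measure_id == "total_activity", ]
    daily <- make_daily(14, measures = "total_activity", value = rnorm(14))
    for (rep in 1:20) {
      drop_n <- sample(0:14, 1)
      d1 <- daily
      d1$value[sample(14, drop_n)] <- NA
      d2 <- d1
      extra <- which(!is.na(d2$value))
      if (length(extra) > 0) d2$value[sample(extra, 1)] <- NA
      e1 <- build_exhaust(segment_biweekly(d1), registry = reg)
      e2 <- build_exhaust(segment_biweekly(d2), registry = reg)
      cols <- names(feature_sources(e1))
      became_present <- is.na(unlist(e1[1, cols])) & !is.na(unlist(e2[1, cols]))
      expect_false(any(became_present))
    }
  })
})

test_that("unknown measure ids in the daily table are an error", {
  daily <- make_daily(14, measures = "not_registered")
  expect_error(build_exhaust(segment_biweekly(daily)), "not_registered")
})

test_that("registry is consistent with what the extractors emit", {
  rec <- scripted_recording()
  daily <- extract_daily_measures(rec)
  reg <- measure_registry()
  expect_true(all(daily$measure_id %in% reg$measure_id))
  expect_equal(anyDuplicated(reg$measure_id), 0)
  agg <- reg$measure_id[reg$granularity %in% c("daily", "nightly")]
  expect_setequal(unique(daily$measure_id), agg)
})

test_that("user measures can be registered once and flow into the exhaust", {
  on.exit(reset_measure_registry(), add = TRUE)
  expect_error(register_measure("hr_mean", "bed"), "already")
  register_measure("custom_x", "pir",
    unit = "count",
    description = "constant test measure",
    extractor = function(rec, day) 42
  )
  rec <- simulate_participant(routine_params(), days = 15, seed = 3)
  ex <- digital_exhaust(rec)
  expect_true("mean_custom_x" %in% names(ex))
  expect_equal(ex$mean_custom_x[1], 42)
})
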