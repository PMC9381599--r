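test_that("averaged scores dichotomize against the validated cut-offs", {
  rules <- cutoff_rules()
  rule_of <- function(a) rules[rules$assessment == a, ]
  expect_equal(dichotomize(14.5, rule_of("TUG")), 1L) # pooled-mean-like TUG
  expect_equal(dichotomize(20.5, rule_of("MoCA")), 1L)
  expect_equal(dichotomize(3.1, rule_of("GDS")), 0L)
  expect_equal(dichotomize(c(10, 14), rule_of("TUG")), 1L) # mean 12 crosses
  expect_error(dichotomize(numeric(0), rule_of("TUG")), "at least one")
})

make_vectors <- function(ids, n_seg = 2) {
  rows <- tidyr::expand_grid(participant_id = ids, segment_index = 0:(n_seg - 1))
  rows$m_a <- seq_len(nrow(rows))
  rows$m_b <- 1
  structure(rows,
    feature_sources = c(m_a = "pir_door", m_b = "bed"),
    class = c("exhaust_tbl", class(rows))
  )
}

test_that("label matching averages scores and annotates nearest assessments", {
  vectors <- make_vectors(c("p1", "p2"))
  assessments <- tibble::tibble(
    participant_id = c("p1", "p1", "p2"),
    assessment = "MoCA",
    date = as.Date(c("2021-03-05", "2021-06-01", "2021-03-05")),
    score = c(20, 28, 27)
  )
  rule <- cutoff_rules()[cutoff_rules()$assessment == "MoCA", ]
  ds <- match_labels(vectors, assessments, rule,
    segment_origin = c(p1 = as.Date("2021-03-01"), p2 = as.Date("2021-03-01"))
  )
  # p1 mean 24 -> 0; p2 27 -> 0 is wrong side? 27 >= 23 -> 0
  expect_equal(unique(ds$label[ds$participant_id == "p1"]), 0L)
  # segment 0 midpoint Mar 8 nearest Mar 5; segment 1 midpoint Mar 22 nearer Mar 5 too
  expect_equal(ds$matched_date[ds$participant_id == "p1"], rep(as.Date("2021-03-05"), 2))

  # equidistant records resolve to the earlier one
  assessments2 <- tibble::tibble(
    participant_id = "p1", assessment = "MoCA",
    date = as.Date("2021-03-08") + c(-2, 2), score = c(20, 26)
  )
  ds2 <- match_labels(make_vectors("p1", 1), assessments2, rule,
    segment_origin = c(p1 = as.Date("2021-03-01"))
  )
  expect_equal(ds2$matched_date, as.Date("2021-03-06"))

  # participants without the assessment are dropped with a message
  expect_message(
    ds3 <- match_labels(make_vectors(c("p1", "p3")), assessments, rule,
      segment_origin = c(p1 = as.Date("2021-03-01"), p3 = as.Date("2021-03-01"))
    ),
    "dropping 1"
  )
  expect_false("p3" %in% ds3$participant_id)
})

test_that("segment validity filters per sensor system", {
  ds <- make_tiny_coa_dataset()
  expect_equal(nrow(filter_valid_segments(ds)), nrow(ds)) # 0% missing

  ds_bad <- ds
  ds_bad$f_bed[1] <- NA # 100% of the bed block missing in row 1
  kept <- filter_valid_segments(ds_bad)
  expect_equal(nrow(kept), nrow(ds) - 1)

  # 29% missing in a 7-column block stays under the default threshold
  wide <- ds
  for (i in 1:7) wide[[paste0("bed_extra", i)]] <- rnorm(nrow(ds))
  src <- attr(wide, "feature_sources")
  src[paste0("bed_extra", 1:7)] <- "bed"
  attr(wide, "feature_sources") <- src
  attr(wide, "feature_cols") <- names(src)
  wide$bed_extra1[1] <- NA
  wide$bed_extra2[1] <- NA # 2/8 = 25% of bed block missing
  expect_equal(nrow(filter_valid_segments(wide)), nrow(wide))
  # the weaker "valid fraction >= threshold" reading keeps even worse rows
  worse <- wide
  for (i in 1:5) worse[[paste0("bed_extra", i)]][2] <- NA # 5/8 missing in row 2
  expect_lt(nrow(filter_valid_segments(worse)), nrow(worse))
  expect_equal(nrow(filter_valid_segments(worse, variant = "per_system_valid")), nrow(worse))
})

test_that("cohort-biased measures are flagged; neutral ones are not", {
  withr::with_seed(55, {
    ds <- make_tiny_coa_dataset(n_part = 20, n_seg = 2)
    ds$f_noise1 <- ds$cohort + rnorm(nrow(ds), 0, 0.01) # cohort proxy
    flags <- screen_cohort_bias(ds)
    expect_true(flags$flagged[flags$measure_id == "f_noise1"])
    expect_false(flags$flagged[flags$measure_id == "f_noise2"])
    auc2 <- flags$cohort_auc[flags$measure_id == "f_noise2"]
    expect_lt(abs(auc2 - 0.5), 0.25)
    manual <- screen_cohort_bias(ds, manual_exclude = "f_bed")
    expect_true(manual$flagged[manual$measure_id == "f_bed"])
    pruned <- exclude_measures(ds, c("f_noise1", "f_bed"))
    expect_false(any(c("f_noise1", "f_bed") %in% names(pruned)))
    expect_false(any(c("f_noise1", "f_bed") %in% names(feature_sources(pruned))))
  })
})

test_that("soft voting averages per participant", {
  probs <- tibble::tibble(
    participant_id = c("a", "a", "b", "c", "c", "c"),
    prob = c(0.2, 0.8, 0.7, 0.1, 0.2, 0.3)
  )
  v <- participant_soft_vote(probs)
  expect_equal(v$prob[v$participant_id == "a"], 0.5)
  expect_equal(v$prob[v$participant_id == "b"], 0.7)
  expect_equal(v$prob[v$participant_id == "c"], 0.2)
  expect_equal(participant_soft_vote(list(a = c(0.2, 0.8))), c(a = 0.5))
  expect_error(participant_soft_vote(list(a = numeric(0))), "at least one")
})

test_that("classification metrics match hand and brute-force values", {
  expect_equal(evaluate_classification(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)),
    list(roc_auc = 1, pr_auc = 1))
  expect_equal(rank_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(rank_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1)), 0.75)
  expect_warning(m <- evaluate_classification(c(1, 1), c(0.5, 0.6)), "one class")
  expect_true(is.na(m$roc_auc))

  withr::with_seed(66, {
    for (i in 1:200) {
      n <- sample(4:20, 1)
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))
      p <- round(runif(n), sample(1:3, 1)) # rounded -> ties occur
      expect_equal(rank_auc(y, p), bf_auc(y, p), tolerance = 1e-12)
    }
  })
})

test_that("iteration summaries give mean and CI half-width", {
  s <- summarize_ci(rep(0.7, 100))
  expect_equal(s$mean, 0.7)
  expect_equal(s$half_width, 0)
  x <- rep(c(0, 1), each = 50)
  s2 <- summarize_ci(x)
  expect_equal(s2$mean, 0.5)
  expect_equal(s2$half_width, qnorm(0.975) * sd(x) / 10, tolerance = 1e-12)
  expect_lt(
    summarize_ci(c(0.6, 0.7, 0.8), level = 0.95)$half_width,
    summarize_ci(c(0.6, 0.7, 0.8), level = 0.99)$half_width
  )
  expect_error(summarize_ci(0.5), "at least 2")
})

test_that("the resampling evaluation is deterministic and leakage-free", {
  ds <- make_tiny_coa_dataset()
  r1 <- run_simulation(ds,
    scenario = "exhaust", n_iterations = 3,
    search_trials = 2, seed = 7
  )
  r2 <- run_simulation(ds,
    scenario = "exhaust", n_iterations = 3,
    search_trials = 2, seed = 7
  )
  expect_equal(r1$metrics, r2$metrics, tolerance = 1e-12)
  expect_true(all(r1$metrics$roc_auc >= 0 & r1$metrics$roc_auc <= 1))
  expect_equal(nrow(r1$metrics), 3)
  expect_equal(length(r1$shap), 3)
  expect_setequal(colnames(r1$shap[[1]]), setdiff(names(feature_sources(ds)), c("age", "sex", "cohort")))
  expect_equal(glance(r1)$scenario, "exhaust")
  expect_equal(nrow(tidy(r1)), 3)
  # demographics-only scenario uses exactly the demographic columns
  rd <- run_simulation(ds, scenario = "demographics", n_iterations = 2,
    search_trials = 2, seed = 1)
  expect_setequal(rd$feature_cols, c("age", "sex", "cohort"))
  expect_error(
    run_simulation(make_tiny_coa_dataset(n_part = 3), n_iterations = 1, seed = 1),
    "2 participants per class"
  )
})
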