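test_that("global SHAP follows the sum-of-mean-absolute aggregation", {
  one <- matrix(c(1, -1), 2, 1, dimnames = list(NULL, "m1"))
  g1 <- global_shap(list(one))
  expect_equal(g1$shap_global, 1)

  g2 <- global_shap(list(one, one))
  expect_equal(g2$shap_global, 2) # additivity over iterations

  withr::with_seed(12, {
    mats <- lapply(1:5, function(i) {
      matrix(rnorm(6 * 4), 6, 4, dimnames = list(NULL, paste0("m", 1:4)))
    })
    g <- global_shap(mats)
    oracle <- bf_global_shap(mats)
    expect_equal(setNames(g$shap_global, g$measure_id), oracle[g$measure_id],
      tolerance = 1e-12
    )
    # permutation invariance + exact additivity over disjoint sets
    expect_equal(global_shap(rev(mats))$shap_global, g$shap_global, tolerance = 1e-15)
    ga <- global_shap(mats[1:2])
    gb <- global_shap(mats[3:5])
    ga_v <- setNames(ga$shap_global, ga$measure_id)
    gb_v <- setNames(gb$shap_global, gb$measure_id)
    g_v <- setNames(g$shap_global, g$measure_id)
    expect_equal(g_v, ga_v[names(g_v)] + gb_v[names(g_v)], tolerance = 1e-15)
  })

  expect_equal(g1$rank, 1L)
  odd <- matrix(1, 2, 2, dimnames = list(NULL, c("m1", "mX")))
  expect_error(global_shap(list(one, odd)), "inconsistent")
  expect_warning(gu <- global_shap(list(one, odd), union = TRUE), "contribute 0")
  expect_equal(gu$shap_global[gu$measure_id == "mX"], 1)
})

test_that("beeswarm export satisfies local accuracy and the remainder rule", {
  ds <- make_tiny_coa_dataset(n_part = 16, n_seg = 3)
  model <- fit_full_model(ds, scenario = "both", config = list(
    nrounds = 40, max_depth = 3, eta = 0.2, subsample = 1,
    colsample_bytree = 1, min_child_weight = 1
  ))
  bs <- beeswarm_export(model, ds, top_k = 3)
  expect_setequal(unique(bs$feature[bs$rank <= 3]), unique(bs$feature)[1:3])
  expect_equal(sort(unique(bs$rank)), 1:4)
  # local accuracy: per-row sum of exported SHAP + base = raw margin
  X <- as.matrix(ds[, attr(model, "feature_cols")])
  margin <- predict(model, xgboost::xgb.DMatrix(X, missing = NA), outputmargin = TRUE)
  per_row <- tapply(bs$shap_value, bs$sample, sum) + attr(bs, "base_value")
  expect_equal(as.numeric(per_row[as.character(seq_along(margin))]), margin, tolerance = 1e-5)

  all_k <- beeswarm_export(model, ds, top_k = length(attr(model, "feature_cols")))
  expect_true(all(all_k$shap_value[all_k$feature == "sum_of_remaining"] == 0))
  expect_warning(clamped <- beeswarm_export(model, ds, top_k = 1000), "clamped")
  expect_equal(length(unique(clamped$feature)), 7 + 1)
})

test_that("group averaging z-normalises then contrasts outcome groups", {
  vectors <- structure(
    tibble::tibble(
      participant_id = c("a", "b"), segment_index = 0L,
      m1 = c(3, -3), m2 = c(1, 1)
    ),
    feature_sources = c(m1 = "pir_door", m2 = "bed")
  )
  g <- group_average_exhaust(vectors, c(a = 1, b = 0))
  expect_equal(g$mean_negative_outcome[g$measure_id == "m1"], 1)
  expect_equal(g$mean_positive_outcome[g$measure_id == "m1"], -1)
  expect_equal(g$mean_negative_outcome[g$measure_id == "m2"], 0) # constant measure

  # three-participant worked case: means (2,4,9) -> z -> group means
  v3 <- structure(
    tibble::tibble(
      participant_id = rep(c("a", "b", "c"), each = 2), segment_index = rep(0:1, 3),
      m1 = c(1, 3, 4, 4, 9, NA)
    ),
    feature_sources = c(m1 = "pir_door")
  )
  g3 <- group_average_exhaust(v3, c(a = 0, b = 0, c = 1))
  mu <- mean(c(2, 4, 9))
  sg <- sqrt(mean((c(2, 4, 9) - mu)^2))
  expect_equal(g3$mean_negative_outcome, (9 - mu) / sg, tolerance = 1e-12)
  expect_equal(g3$mean_positive_outcome, mean(((c(2, 4) - mu)) / sg), tolerance = 1e-12)

  # identical groups collapse to zero after z-normalisation
  v4 <- structure(
    tibble::tibble(
      participant_id = c("a", "b"), segment_index = 0L, m1 = c(5, 5)
    ),
    feature_sources = c(m1 = "pir_door")
  )
  g4 <- group_average_exhaust(v4, c(a = 1, b = 0))
  expect_equal(g4$mean_negative_outcome, 0)
  expect_equal(g4$mean_positive_outcome, 0)
})
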