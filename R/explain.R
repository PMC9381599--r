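#' Global SHAP importance across simulation iterations
#'
#' Aggregates per-iteration SHAP matrices into the global importance of
#' each digital measure: the mean absolute SHAP value of the measure over
#' one iteration's test samples, summed over all iterations,
#' \deqn{SHAP^{global}_m = \sum_i mean(|SHAP^i_m|),}
#' with a dense descending rank. The aggregate is additive over disjoint
#' iteration sets.
#'
#' @param matrices List of SHAP matrices (rows = test samples, columns =
#'   features, log-odds units), e.g. the `shap` element of a
#'   [run_simulation()] result.
#' @param union If `TRUE`, iterations missing a feature column contribute
#'   0 for it (with a warning); otherwise inconsistent columns are an
#'   error.
#' @return Tibble of class `global_importance`:
#'   `measure_id, shap_global, rank`.
#' @export
global_shap <- function(matrices, union = FALSE) {
  matrices <- matrices[!vapply(matrices, is.null, logical(1))]
  if (length(matrices) == 0L) abort("need at least one SHAP matrix")
  cols_list <- lapply(matrices, colnames)
  all_cols <- unique(unlist(cols_list))
  consistent <- all(vapply(cols_list, function(cc) identical(sort(cc), sort(all_cols)), logical(1)))
  if (!consistent) {
    if (!union) abort("SHAP matrices have inconsistent columns (use union = TRUE to pool)")
    warn("inconsistent SHAP columns; missing features contribute 0")
  }
  total <- setNames(rep(0, length(all_cols)), all_cols)
  for (m in matrices) {
    mam <- colMeans(abs(m))
    total[colnames(m)] <- total[colnames(m)] + mam
  }
  out <- tibble(measure_id = names(total), shap_global = unname(total)) |>
    arrange(desc(.data$shap_global)) |>
    mutate(rank = dense_rank(desc(.data$shap_global)))
  structure(out, class = c("global_importance", class(out)))
}

#' @rdname global_shap
#' @param object A `global_importance` table.
#' @param top_n Number of measures displayed.
#' @param ... Unused.
#' @method autoplot global_importance
#' @export
autoplot.global_importance <- function(object, top_n = 20, ...) {
  d <- head(object[order(-object$shap_global), ], top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$shap_global,
    y = stats::reorder(.data$measure_id, .data$shap_global)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "global SHAP (sum of mean |SHAP|)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Fit one full-data model for direction-of-effect inspection
#'
#' Beeswarm-style displays use a single model trained on the entire
#' dataset with fixed hyperparameters (defaults: search-space midpoints),
#' deliberately distinct from the 100 resampling models behind the global
#' ranking.
#'
#' @param dataset A `coa_dataset`.
#' @param scenario Feature scenario, see [run_simulation()].
#' @param config Hyperparameters (default [midpoint_xgb_config()]).
#' @param seed,nthread Reproducibility controls.
#' @return An `xgb.Booster` with a `feature_cols` attribute.
#' @export
fit_full_model <- function(dataset, scenario = "exhaust",
                           config = midpoint_xgb_config(), seed = 1, nthread = 1) {
  feats <- scenario_features(dataset, scenario)
  X <- as.matrix(dataset[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  model <- fit_xgb(X, dataset$label, config, nthread = nthread, seed = seed)
  attr(model, "feature_cols") <- feats
  model
}

#' Export beeswarm data: per-sample SHAP values of the top measures
#'
#' Long-format records `(sample, feature, shap_value, feature_value,
#' rank)` for the `top_k` features by mean absolute SHAP of the given
#' model, plus one synthetic `sum_of_remaining` feature holding the
#' row-sum of all other features' SHAP values. Per row, the exported SHAP
#' values (top k + remainder) plus the base value reproduce the model's
#' log-odds output exactly (TreeSHAP local accuracy).
#'
#' @param model Result of [fit_full_model()] (or any booster with a
#'   `feature_cols` attribute).
#' @param dataset The `coa_dataset` the model was trained on.
#' @param top_k Number of individually exported features (default 9);
#'   values above the feature count are clamped with a warning.
#' @param nthread Threads.
#' @return Tibble with attribute `base_value`.
#' @export
beeswarm_export <- function(model, dataset, top_k = 9, nthread = 1) {
  feats <- attr(model, "feature_cols")
  X <- as.matrix(dataset[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  ct <- predict_xgb(model, X, nthread, contrib = TRUE)
  bias <- ct[, ncol(ct)]
  ct <- ct[, -ncol(ct), drop = FALSE]
  colnames(ct) <- feats
  if (top_k > length(feats)) {
    warn(sprintf("top_k = %d exceeds %d features; clamped", top_k, length(feats)))
    top_k <- length(feats)
  }
  imp <- colMeans(abs(ct))
  top <- names(sort(imp, decreasing = TRUE))[seq_len(top_k)]
  rest <- setdiff(feats, top)
  rows <- lapply(seq_along(top), function(k) {
    tibble(
      sample = seq_len(nrow(ct)), feature = top[k],
      shap_value = ct[, top[k]],
      feature_value = X[, top[k]],
      rank = k
    )
  })
  remainder <- tibble(
    sample = seq_len(nrow(ct)), feature = "sum_of_remaining",
    shap_value = if (length(rest) > 0) rowSums(ct[, rest, drop = FALSE]) else rep(0, nrow(ct)),
    feature_value = NA_real_,
    rank = top_k + 1L
  )
  out <- bind_rows(c(rows, list(remainder)))
  attr(out, "base_value") <- bias
  out
}

#' Group-averaged, z-normalised exhaust profiles
#'
#' The heatmap data layer: exhaust vectors are averaged per participant
#' over segments (missing ignored), z-normalised per measure across
#' participants, then averaged within the positive and negative outcome
#' groups. Values above 0 indicate above-cohort-average measures.
#'
#' @param vectors An `exhaust_tbl` (or `coa_dataset`) with feature
#'   columns.
#' @param labels Named 0/1 vector (participant -> label) or a tibble
#'   `participant_id, label`.
#' @return Tibble `measure_id, mean_negative_outcome, mean_positive_outcome`
#'   (label 1 = negative health outcome). Measures missing for all
#'   participants stay `NA` in both columns.
#' @export
group_average_exhaust <- function(vectors, labels) {
  if (is.data.frame(labels)) labels <- setNames(labels$label, labels$participant_id)
  feat_cols <- names(feature_sources(vectors)) %||%
    setdiff(names(vectors), c("participant_id", "segment_index"))
  per_part <- vectors |>
    group_by(.data$participant_id) |>
    summarise(across(all_of(feat_cols), ~ mean(.x, na.rm = TRUE)), .groups = "drop")
  lab <- labels[per_part$participant_id]
  if (any(is.na(lab))) abort("every participant needs a label")
  if (length(unique(lab)) < 2) abort("need both outcome groups")
  M <- as.matrix(per_part[, feat_cols, drop = FALSE])
  M[is.nan(M)] <- NA
  mu <- colMeans(M, na.rm = TRUE)
  # population SD: a two-participant {+a, -a} pair must map to z = +/-1
  sg <- apply(M, 2, function(cc) {
    v <- cc[!is.na(cc)]
    if (length(v) == 0) NA_real_ else sqrt(mean((v - mean(v))^2))
  })
  Z <- sweep(sweep(M, 2, mu), 2, ifelse(sg > 0 | is.na(sg), sg, 1), "/")
  tibble(
    measure_id = feat_cols,
    mean_negative_outcome = unname(colMeans(Z[lab == 1, , drop = FALSE], na.rm = TRUE)),
    mean_positive_outcome = unname(colMeans(Z[lab == 0, , drop = FALSE], na.rm = TRUE))
  ) |>
    mutate(across(c("mean_negative_outcome", "mean_positive_outcome"), ~ ifelse(is.nan(.x), NA_real_, .x)))
}

#' Heatmap of group-averaged exhaust profiles
#'
#' @param groups Output of [group_average_exhaust()].
#' @param top_n Measures shown, ordered by group contrast.
#' @return A ggplot object.
#' @export
plot_exhaust_heatmap <- function(groups, top_n = 40) {
  g <- groups[!is.na(groups$mean_negative_outcome), ]
  g <- head(g[order(-abs(g$mean_negative_outcome - g$mean_positive_outcome)), ], top_n)
  long <- tidyr::pivot_longer(g, c("mean_negative_outcome", "mean_positive_outcome"),
    names_to = "group", values_to = "z"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$group,
    y = stats::reorder(.data$measure_id, abs(.data$z)), fill = .data$z
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal()
}
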