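#' Rank-based ROC AUC and step-integrated precision-recall AUC
#'
#' `roc_auc` uses the rank (Mann-Whitney) identity with average ranks for
#' ties — equal to the trapezoidal area under the ROC curve. `pr_auc` is
#' the step integration of the precision-recall curve (average precision),
#' with tied scores processed as blocks; the positive class is the
#' negative health outcome (label 1).
#'
#' @param y_true Integer 0/1 labels.
#' @param y_prob Predicted probabilities/scores.
#' @return `evaluate_classification()` returns a list with `roc_auc` and
#'   `pr_auc`; both are `NA` (with a warning) when only one class is
#'   present.
#' @export
evaluate_classification <- function(y_true, y_prob) {
  stopifnot(length(y_true) == length(y_prob))
  if (length(unique(y_true)) < 2) {
    warn("only one class present; metrics undefined")
    return(list(roc_auc = NA_real_, pr_auc = NA_real_))
  }
  list(roc_auc = rank_auc(y_true, y_prob), pr_auc = pr_auc(y_true, y_prob))
}

#' @rdname evaluate_classification
#' @export
rank_auc <- function(y_true, y_prob) {
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  r <- rank(y_prob)
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname evaluate_classification
#' @export
pr_auc <- function(y_true, y_prob) {
  o <- order(y_prob, decreasing = TRUE)
  y <- y_true[o]
  s <- y_prob[o]
  pos <- sum(y == 1)
  blocks <- cumsum(!duplicated(s))
  tp <- 0
  fp <- 0
  prev_rec <- 0
  ap <- 0
  for (b in unique(blocks)) {
    sel <- blocks == b
    tp <- tp + sum(y[sel] == 1)
    fp <- fp + sum(y[sel] == 0)
    prec <- tp / (tp + fp)
    rec <- tp / pos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

#' Combine segment-level predictions into participant scores (soft voting)
#'
#' @param segment_probs Either a tibble with columns `participant_id` and
#'   `prob` (one row per segment) or a named list of per-participant
#'   probability vectors.
#' @return Tibble `participant_id, prob` with the arithmetic mean per
#'   participant (or a named numeric vector for list input).
#' @export
participant_soft_vote <- function(segment_probs) {
  if (is.data.frame(segment_probs)) {
    if (nrow(segment_probs) == 0L) abort("no predictions to vote over")
    segment_probs |>
      group_by(.data$participant_id) |>
      summarise(prob = mean(.data$prob), .groups = "drop")
  } else {
    if (any(vapply(segment_probs, length, integer(1)) == 0L)) {
      abort("every participant needs at least one prediction")
    }
    vapply(segment_probs, mean, numeric(1))
  }
}

#' Mean and confidence-interval half-width over simulation iterations
#'
#' @param metric_samples Numeric vector of per-iteration metric values
#'   (at least 2).
#' @param level Confidence level (default 0.95).
#' @param method `"normal"`: half-width `= z * sd / sqrt(n)`;
#'   `"percentile"`: half the distance between the matching sample
#'   quantiles.
#' @return List with `mean` and `half_width`.
#' @export
summarize_ci <- function(metric_samples, level = 0.95, method = c("normal", "percentile")) {
  method <- match.arg(method)
  x <- metric_samples[!is.na(metric_samples)]
  if (length(x) < 2) abort("need at least 2 metric samples")
  if (method == "normal") {
    z <- qnorm(1 - (1 - level) / 2)
    list(mean = mean(x), half_width = z * sd(x) / sqrt(length(x)))
  } else {
    qs <- quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    list(mean = mean(x), half_width = (qs[2] - qs[1]) / 2)
  }
}

#' Random-search configuration sampler for the gradient-boosted classifier
#'
#' Ranges sized for small-n tabular gradient boosting (tens of
#' participants, a few hundred segments): tree count 50-250, depth 2-6,
#' learning rate log-uniform on `[0.03, 0.3]`, subsample `[0.5, 1]`,
#' column subsample `[0.3, 1]`, minimum child weight 1-10. Deeper/longer
#' boosters mostly overfit at this sample size.
#'
#' @return A named list with one sampled hyperparameter configuration.
#' @export
sample_xgb_config <- function() {
  list(
    nrounds = sample(50:250, 1),
    max_depth = sample(2:6, 1),
    eta = exp(runif(1, log(0.03), log(0.3))),
    subsample = runif(1, 0.5, 1),
    colsample_bytree = runif(1, 0.3, 1),
    min_child_weight = sample(1:10, 1)
  )
}

#' Midpoint configuration of the search space (for single full-data models)
#' @return A named hyperparameter list.
#' @export
midpoint_xgb_config <- function() {
  list(
    nrounds = 150, max_depth = 4, eta = exp(mean(log(c(0.03, 0.3)))),
    subsample = 0.75, colsample_bytree = 0.65, min_child_weight = 5
  )
}

fit_xgb <- function(X, y, config, nthread = 1, seed = 0) {
  dtr <- xgboost::xgb.DMatrix(X, label = y, missing = NA, nthread = nthread)
  params <- list(
    objective = "binary:logistic", eval_metric = "logloss",
    tree_method = "hist", max_bin = 16, # coarse bins: ample for a few hundred rows
    max_depth = config$max_depth, eta = config$eta,
    subsample = config$subsample, colsample_bytree = config$colsample_bytree,
    min_child_weight = config$min_child_weight, nthread = nthread,
    seed = seed
  )
  xgboost::xgb.train(params = params, data = dtr, nrounds = config$nrounds, verbose = 0)
}

predict_xgb <- function(model, X, nthread = 1, contrib = FALSE) {
  dm <- xgboost::xgb.DMatrix(X, missing = NA, nthread = nthread)
  predict(model, dm, predcontrib = contrib)
}

scenario_features <- function(dataset, scenario) {
  src <- feature_sources(dataset)
  demo <- names(src)[src == "demographics"]
  exhaust <- names(src)[src != "demographics"]
  switch(scenario,
    demographics = demo,
    exhaust = exhaust,
    both = c(exhaust, demo),
    abort(sprintf("unknown scenario '%s'", scenario))
  )
}

# Stratified participant-level split; returns list(train, test) of ids.
stratified_participant_split <- function(ids, labels, train_frac) {
  train <- character(0)
  for (cl in unique(labels)) {
    g <- ids[labels == cl]
    k <- min(max(round(train_frac * length(g)), 1L), length(g) - 1L)
    train <- c(train, sample(g, k))
  }
  list(train = train, test = setdiff(ids, train))
}

# Stratified fold assignment over participants.
stratified_folds <- function(ids, labels, k) {
  fold <- setNames(integer(length(ids)), ids)
  for (cl in unique(labels)) {
    g <- sample(ids[labels == cl])
    fold[g] <- rep_len(seq_len(k), length(g))
  }
  fold
}

#' Participant-stratified resampling evaluation of a digital COA
#'
#' The core evaluation loop: in each iteration, participants are split
#' 70/30 stratified by label (all segments of a participant stay on one
#' side, so no leakage is possible); hyperparameters of a gradient-boosted
#' tree classifier with native missing-value handling are tuned by random
#' search with stratified k-fold cross-validation *within* the training
#' participants (selection metric: segment-level ROC AUC); the winning
#' configuration is refit on the full training split; test-segment
#' probabilities are soft-voted into participant scores; ROC AUC and
#' PrAUC are recorded, along with the exact TreeSHAP contribution matrix
#' of the test segments for downstream biomarker ranking.
#'
#' @param dataset A `coa_dataset` from [match_labels()].
#' @param scenario `"demographics"`, `"exhaust"`, or `"both"`.
#' @param n_iterations Number of resampling iterations (default 100).
#' @param train_frac Training fraction of participants (default 0.70).
#' @param cv_folds Inner cross-validation folds (default 3).
#' @param search_trials Random-search trials per iteration (default 50).
#' @param seed Integer seed; identical inputs give identical results.
#' @param config_sampler Function drawing one hyperparameter
#'   configuration (default [sample_xgb_config()]).
#' @param keep_shap Retain per-iteration SHAP matrices (default `TRUE`).
#' @param nthread Threads for the booster (default 1, fully
#'   deterministic).
#' @return A `coa_simulation` object: `metrics` (per-iteration tibble),
#'   `summary` (mean and 95% CI half-width per metric), `shap` (list of
#'   per-iteration contribution matrices with a `base_value` attribute),
#'   `feature_cols`, `scenario`, `resampled_iterations`.
#' @export
run_simulation <- function(dataset, scenario = c("exhaust", "demographics", "both"),
                           n_iterations = 100, train_frac = 0.70, cv_folds = 3,
                           search_trials = 50, seed = 1,
                           config_sampler = sample_xgb_config,
                           keep_shap = TRUE, nthread = 1) {
  scenario <- match.arg(scenario)
  feats <- scenario_features(dataset, scenario)
  X <- as.matrix(dataset[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  y <- dataset$label
  pid <- dataset$participant_id
  p_tbl <- distinct(tibble(participant_id = pid, label = y))
  if (min(table(p_tbl$label)) < 2 || length(unique(p_tbl$label)) < 2) {
    abort("need at least 2 participants per class")
  }

  with_local_seed(seed, {
    roc <- pr <- rep(NA_real_, n_iterations)
    shap <- if (keep_shap) vector("list", n_iterations) else NULL
    best_configs <- vector("list", n_iterations)
    resampled <- 0L

    for (it in seq_len(n_iterations)) {
      for (attempt in seq_len(100L)) {
        sp <- stratified_participant_split(p_tbl$participant_id, p_tbl$label, train_frac)
        tr_lab <- p_tbl$label[match(sp$train, p_tbl$participant_id)]
        te_lab <- p_tbl$label[match(sp$test, p_tbl$participant_id)]
        if (length(unique(tr_lab)) == 2 && length(unique(te_lab)) == 2) break
        resampled <- resampled + 1L
        if (attempt == 100L) abort("unsatisfiable stratification: a class cannot reach both splits")
      }
      stopifnot(length(intersect(sp$train, sp$test)) == 0L) # leakage guard

      fold <- stratified_folds(sp$train, tr_lab, cv_folds)
      configs <- lapply(seq_len(search_trials), function(i) config_sampler())
      fit_seeds <- sample.int(.Machine$integer.max, search_trials * cv_folds + 1L)
      cv_auc <- vapply(seq_along(configs), function(ci) {
        aucs <- vapply(seq_len(cv_folds), function(f) {
          va_ids <- names(fold)[fold == f]
          tr_ids <- setdiff(sp$train, va_ids)
          tr_rows <- pid %in% tr_ids
          va_rows <- pid %in% va_ids
          if (length(unique(y[tr_rows])) < 2 || length(unique(y[va_rows])) < 2) {
            return(NA_real_)
          }
          m <- fit_xgb(X[tr_rows, , drop = FALSE], y[tr_rows], configs[[ci]],
            nthread = nthread, seed = fit_seeds[(ci - 1) * cv_folds + f]
          )
          rank_auc(y[va_rows], predict_xgb(m, X[va_rows, , drop = FALSE], nthread))
        }, numeric(1))
        mean(aucs, na.rm = TRUE)
      }, numeric(1))
      best <- configs[[which.max(cv_auc)]]
      best_configs[[it]] <- best

      tr_rows <- pid %in% sp$train
      te_rows <- pid %in% sp$test
      model <- fit_xgb(X[tr_rows, , drop = FALSE], y[tr_rows], best,
        nthread = nthread, seed = fit_seeds[length(fit_seeds)]
      )
      probs <- predict_xgb(model, X[te_rows, , drop = FALSE], nthread)
      voted <- participant_soft_vote(tibble(participant_id = pid[te_rows], prob = probs))
      y_part <- p_tbl$label[match(voted$participant_id, p_tbl$participant_id)]
      metrics <- evaluate_classification(y_part, voted$prob)
      roc[it] <- metrics$roc_auc
      pr[it] <- metrics$pr_auc

      if (keep_shap) {
        ct <- predict_xgb(model, X[te_rows, , drop = FALSE], nthread, contrib = TRUE)
        bias <- ct[, ncol(ct), drop = TRUE]
        ct <- ct[, -ncol(ct), drop = FALSE]
        colnames(ct) <- feats
        attr(ct, "base_value") <- mean(bias)
        shap[[it]] <- ct
      }
    }
    if (resampled > 0) inform(sprintf("%d split(s) resampled to keep both classes present", resampled))

    structure(
      list(
        metrics = tibble(iteration = seq_len(n_iterations), roc_auc = roc, pr_auc = pr),
        summary = tibble(
          metric = c("roc_auc", "pr_auc"),
          mean = c(summarize_ci(roc)$mean, summarize_ci(pr)$mean),
          ci_half_width = c(summarize_ci(roc)$half_width, summarize_ci(pr)$half_width)
        ),
        shap = shap, best_configs = best_configs,
        feature_cols = feats, scenario = scenario,
        assessment = attr(dataset, "assessment"),
        resampled_iterations = resampled
      ),
      class = "coa_simulation"
    )
  })
}

#' @export
print.coa_simulation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<coa_simulation> %s / %s: %d iterations\n  ROC AUC %.3f +/- %.3f | PrAUC %.3f +/- %.3f\n",
    x$assessment %||% "?", x$scenario, nrow(x$metrics),
    s$mean[1], s$ci_half_width[1], s$mean[2], s$ci_half_width[2]
  ))
  invisible(x)
}

#' @rdname run_simulation
#' @param x A `coa_simulation`.
#' @param ... Unused.
#' @method tidy coa_simulation
#' @export
tidy.coa_simulation <- function(x, ...) x$metrics

#' @rdname run_simulation
#' @method glance coa_simulation
#' @export
glance.coa_simulation <- function(x, ...) {
  tibble(
    assessment = x$assessment %||% NA_character_, scenario = x$scenario,
    n_iterations = nrow(x$metrics),
    roc_auc_mean = x$summary$mean[1], roc_auc_ci = x$summary$ci_half_width[1],
    pr_auc_mean = x$summary$mean[2], pr_auc_ci = x$summary$ci_half_width[2]
  )
}

#' @rdname run_simulation
#' @param object A `coa_simulation`.
#' @method autoplot coa_simulation
#' @export
autoplot.coa_simulation <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, c("roc_auc", "pr_auc"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(
      x = NULL, y = "metric value",
      title = sprintf("%s (%s scenario)", object$assessment %||% "", object$scenario)
    ) +
    ggplot2::theme_minimal()
}
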