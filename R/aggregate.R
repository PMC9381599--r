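#' Summary-statistic sets for bi-weekly aggregation
#'
#' The closed set of per-segment summary statistics applied to daily and
#' nightly base measures: quantiles `q10/q25/q50/q75/q90` (q50 = median),
#' `iqr`, `mean`, `coefvar` (coefficient of variation), and the quantile-
#' based robust skewness and kurtosis `sk3` and `kr3` in the Kim-White
#' naming convention.
#'
#' @param stats Character vector drawn from the closed set.
#' @return Character vector of class-checked statistic names.
#' @export
summary_statset <- function(stats = c(
                              "q10", "q25", "q50", "q75", "q90", "iqr",
                              "mean", "coefvar", "kr3", "sk3"
                            )) {
  allowed <- c("q10", "q25", "q50", "q75", "q90", "iqr", "mean", "coefvar", "kr3", "sk3")
  bad <- setdiff(stats, allowed)
  if (length(bad) > 0) abort(sprintf("unknown summary statistic(s): %s", paste(bad, collapse = ", ")))
  stats
}

#' Summarize up to 14 daily values with the bi-weekly statistic set
#'
#' Statistics are computed over present (non-`NA`) values only. Quantiles
#' use linear interpolation between closest order statistics;
#' `iqr = q75 - q25`; `coefvar` is the sample SD (n-1 denominator) over the
#' mean, `NA` when `|mean| < 1e-12`; `sk3`/`kr3` follow
#' [robust_skew_sk3()] and [robust_kurt_kr3()]. With fewer than two present
#' values all statistics are `NA` except `mean` and `q50` when exactly one
#' value is present.
#'
#' @param values Numeric vector (with `NA` for missing days).
#' @param statset Statistic names from [summary_statset()].
#' @return Named numeric vector, one element per requested statistic.
#' @export
summarize_values <- function(values, statset = summary_statset()) {
  x <- values[!is.na(values)]
  out <- setNames(rep(NA_real_, length(statset)), statset)
  n <- length(x)
  if (n == 0L) return(out)
  if (n == 1L) {
    if ("mean" %in% statset) out["mean"] <- x
    if ("q50" %in% statset) out["q50"] <- x
    return(out)
  }
  qs <- quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7, names = FALSE)
  vals <- list(
    q10 = qs[1], q25 = qs[2], q50 = qs[3], q75 = qs[4], q90 = qs[5],
    iqr = qs[4] - qs[2], mean = mean(x)
  )
  m <- mean(x)
  vals$coefvar <- if (abs(m) < 1e-12) NA_real_ else sd(x) / m
  vals$sk3 <- robust_skew_sk3(x)
  vals$kr3 <- robust_kurt_kr3(x)
  for (s in statset) out[s] <- vals[[s]]
  out
}

#' Robust skewness SK3 (Groeneveld-Meeden form)
#'
#' `sk3 = (mean - median) / mean(|x - median|)`; exactly 0 for symmetric
#' samples, bounded in `[-1, 1]`, far less outlier-sensitive than the
#' moment coefficient.
#'
#' @param x Numeric vector; `NA` dropped. Fewer than 3 present values, or a
#'   zero mean absolute deviation, yield `NA`.
#' @return Scalar.
#' @export
robust_skew_sk3 <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) return(NA_real_)
  med <- median(x)
  denom <- mean(abs(x - med))
  if (denom < 1e-12) {
    # constant samples are symmetric: skewness 0, not undefined
    return(if (abs(mean(x) - med) < 1e-12) 0 else NA_real_)
  }
  (mean(x) - med) / denom
}

#' Robust kurtosis KR3 (Hogg form)
#'
#' `kr3 = (U_0.05 - L_0.05) / (U_0.5 - L_0.5) - c`, where `U_a`/`L_a` are
#' means of the upper/lower `a`-fraction of the order statistics
#' (fractional boundary weight) and `c` centers the statistic at 0 for the
#' normal distribution. The default `c = 2.59` matches the analytic normal
#' value `2 * dnorm(qnorm(0.95)) / 0.05 / (2 * dnorm(0)) = 2.585`.
#'
#' @param x Numeric vector; `NA` dropped. Requires at least `min_n`
#'   present values for stability.
#' @param centering Normal-centering constant `c`.
#' @param min_n Stability floor (default 20); fewer values yield `NA`.
#' @return Scalar; `NA` on a zero denominator.
#' @export
robust_kurt_kr3 <- function(x, centering = 2.59, min_n = 20L) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < min_n) return(NA_real_)
  s <- sort(x)
  tail_mean <- function(alpha, upper) {
    k <- alpha * n
    v <- if (upper) rev(s) else s
    kf <- floor(k)
    acc <- sum(v[seq_len(kf)])
    if (k > kf) acc <- acc + (k - kf) * v[kf + 1L]
    acc / k
  }
  denom <- tail_mean(0.5, TRUE) - tail_mean(0.5, FALSE)
  if (abs(denom) < 1e-12) return(NA_real_)
  (tail_mean(0.05, TRUE) - tail_mean(0.05, FALSE)) / denom - centering
}

#' Cut a daily measure table into non-overlapping bi-weekly segments
#'
#' Segments are recording-relative: they start at each participant's first
#' observed date and advance by exactly 14 days; a trailing partial segment
#' is dropped. Per-measure counts of valid (non-`NA`) days are attached.
#'
#' @param daily Long tibble from [extract_daily_measures()] (one or more
#'   participants).
#' @return Nested tibble with columns `participant_id`, `segment_index`
#'   (0-based), `start_date`, `dates` (list of 14 dates), `daily` (list of
#'   the long rows falling in the segment) and `valid_day_count` (list of
#'   named integer vectors).
#' @export
segment_biweekly <- function(daily) {
  empty <- tibble(
    participant_id = character(), segment_index = integer(),
    start_date = as.Date(character()), dates = list(), daily = list(),
    valid_day_count = list()
  )
  if (nrow(daily) == 0L) return(empty)
  out <- list()
  for (pid in unique(daily$participant_id)) {
    d <- daily[daily$participant_id == pid, , drop = FALSE]
    first <- min(d$date)
    n_seg <- (as.integer(max(d$date) - first) + 1L) %/% 14L
    for (s in seq_len(n_seg)) {
      s0 <- first + (s - 1L) * 14L
      dates <- seq(s0, by = "day", length.out = 14L)
      dd <- d[d$date >= s0 & d$date <= s0 + 13L, , drop = FALSE]
      vdc <- tapply(!is.na(dd$value), dd$measure_id, sum)
      out[[length(out) + 1L]] <- tibble(
        participant_id = pid, segment_index = s - 1L, start_date = s0,
        dates = list(dates), daily = list(dd),
        valid_day_count = list(setNames(as.integer(vdc), names(vdc)))
      )
    }
  }
  if (length(out) == 0L) return(empty)
  bind_rows(out)
}

#' Build bi-weekly digital-exhaust vectors
#'
#' For every daily/nightly base measure with at least `min_days` valid days
#' in a segment, emits all summary-statistic derivates (named
#' `<stat>_<base_measure_id>`); below the floor all derivates are `NA`.
#' Per-segment measures (the cosinor family, computed from the raw
#' bi-weekly PIR signal when `rec` is supplied) appear under their bare ids
#' and obey the same `min_days` gate on valid PIR days. The resulting
#' column set is a pure function of `(registry, statset)` — identical
#' across participants and segments.
#'
#' @param segments Output of [segment_biweekly()].
#' @param registry Registry tibble.
#' @param statset Statistic names from [summary_statset()].
#' @param min_days Minimum valid days per measure per segment (default 10).
#' @param rec Optional [home_recording()] supplying raw data for
#'   per-segment measures; without it they are `NA`.
#' @return Wide tibble (class `exhaust_tbl`): `participant_id`,
#'   `segment_index`, one column per derived measure. The attribute
#'   `feature_sources` maps every feature column to its sensor system
#'   (`pir_door` or `bed`).
#' @export
build_exhaust <- function(segments, registry = measure_registry(),
                          statset = summary_statset(), min_days = 10, rec = NULL) {
  agg_reg <- registry[registry$granularity %in% c("daily", "nightly"), , drop = FALSE]
  seg_reg <- registry[registry$granularity == "per_segment", , drop = FALSE]
  known <- registry$measure_id
  for (dd in segments$daily) {
    unknown <- setdiff(unique(dd$measure_id), known)
    if (length(unknown) > 0) {
      abort(sprintf("daily table contains unregistered measure_id(s): %s", paste(unknown, collapse = ", ")))
    }
  }
  feat_cols <- c(
    as.vector(t(outer(statset, agg_reg$measure_id, paste, sep = "_"))),
    seg_reg$measure_id
  )
  src_of <- setNames(ifelse(registry$source == "bed", "bed", "pir_door"), registry$measure_id)
  feature_sources <- setNames(c(
    rep(src_of[agg_reg$measure_id], each = length(statset)),
    src_of[seg_reg$measure_id]
  ), feat_cols)

  vals_mat <- matrix(NA_real_, nrow(segments), length(feat_cols),
    dimnames = list(NULL, feat_cols)
  )
  for (i in seq_len(nrow(segments))) {
    dd <- segments$daily[[i]]
    vdc <- segments$valid_day_count[[i]]
    vals <- setNames(rep(NA_real_, length(feat_cols)), feat_cols)
    for (m in agg_reg$measure_id) {
      if (!is.na(vdc[m]) && !is.null(vdc[m]) && isTRUE(vdc[[m]] >= min_days)) {
        v <- dd$value[dd$measure_id == m]
        st <- summarize_values(v, statset)
        vals[paste0(statset, "_", m)] <- st[statset]
      }
    }
    if (!is.null(rec) && nrow(seg_reg) > 0) {
      tz <- rec$timezone
      s0 <- as.POSIXct(paste(segments$start_date[i], "00:00:00"), tz = tz)
      s1 <- as.POSIXct(paste(segments$start_date[i] + 14L, "00:00:00"), tz = tz)
      pir_days <- vdc["total_activity"]
      if (!is.na(pir_days) && pir_days >= min_days) {
        fit <- fit_cosinor(pir_activity_signal(rec, s0, s1), min_days = min_days, tz = tz)
        cos_map <- c(
          cosinor_mesor = fit$mesor, cosinor_amplitude = fit$amplitude,
          cosinor_acrophase = fit$acrophase, cosinor_rsq = fit$r_squared
        )
        keep <- intersect(names(cos_map), feat_cols)
        vals[keep] <- cos_map[keep]
      }
    }
    vals_mat[i, ] <- vals
  }
  out <- dplyr::bind_cols(
    tibble(
      participant_id = segments$participant_id,
      segment_index = segments$segment_index
    ),
    as_tibble(vals_mat)
  )
  structure(out, feature_sources = feature_sources, class = c("exhaust_tbl", class(out)))
}

#' One-call pipeline: recording to digital-exhaust vectors
#'
#' @inheritParams build_exhaust
#' @inheritParams extract_daily_measures
#' @return An `exhaust_tbl`, see [build_exhaust()].
#' @export
digital_exhaust <- function(rec, registry = measure_registry(),
                            statset = summary_statset(), min_days = 10,
                            min_pir_coverage_h = 20, min_stage_h = 3,
                            min_outing_min = 5) {
  daily <- extract_daily_measures(rec, registry,
    min_pir_coverage_h = min_pir_coverage_h,
    min_stage_h = min_stage_h, min_outing_min = min_outing_min
  )
  segs <- segment_biweekly(daily)
  build_exhaust(segs, registry, statset, min_days = min_days, rec = rec)
}

#' Write exhaust vectors as wide CSV with a provenance sidecar
#'
#' One row per (participant, segment), one column per derived measure,
#' empty cells for missing; the sidecar JSON records the registry, the
#' statistic set and a fingerprint hash of both.
#'
#' @param exhaust An `exhaust_tbl`.
#' @param path CSV output path; the sidecar is written to
#'   `<path>.meta.json`.
#' @param registry,statset Provenance inputs recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_exhaust <- function(exhaust, path, registry = measure_registry(),
                          statset = summary_statset()) {
  readr::write_csv(exhaust, path, na = "")
  meta <- list(
    statset = statset,
    registry = registry,
    fingerprint = rlang::hash(list(registry, statset))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), pretty = TRUE, auto_unbox = TRUE)
  invisible(path)
}

#' Feature-to-sensor-system map of an exhaust table
#'
#' @param exhaust An `exhaust_tbl` (or a `coa_dataset` carrying the same
#'   attribute).
#' @return Named character vector, feature column -> `pir_door`/`bed` (or
#'   `demographics`).
#' @export
feature_sources <- function(exhaust) attr(exhaust, "feature_sources")
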