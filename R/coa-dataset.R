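#' Clinical assessment cut-off rules
#'
#' The validated dichotomization cut-offs mapping each assessment score to
#' a negative health outcome: TUG >= 12 s (fall risk), POMA < 19 points
#' (fall risk), EFS > 5 points (frailty), GDS >= 5 points (depression),
#' MoCA < 23 points (mild cognitive impairment).
#'
#' @return Tibble with columns `assessment`, `comparator`
#'   (`ge`/`gt`/`lt`), `threshold`, `outcome_name`.
#' @export
cutoff_rules <- function() {
  tibble(
    assessment = ASSESSMENTS,
    comparator = c("ge", "lt", "gt", "ge", "lt"),
    threshold = c(12, 19, 5, 5, 23),
    outcome_name = c("fall_risk", "fall_risk", "frailty", "depression", "mci")
  )
}

#' Dichotomize a participant's assessment scores
#'
#' Multiple records of the same assessment are averaged first, then the
#' mean is compared against the cut-off; label 1 encodes the negative
#' health outcome.
#'
#' @param scores Numeric scores (or an assessment-record tibble with a
#'   `score` column) for one participant and one assessment.
#' @param rule One row of [cutoff_rules()].
#' @return Integer 0/1.
#' @export
dichotomize <- function(scores, rule) {
  if (is.data.frame(scores)) scores <- scores$score
  if (length(scores) == 0L) abort("dichotomize requires at least one score")
  m <- mean(scores)
  hit <- switch(rule$comparator,
    ge = m >= rule$threshold,
    gt = m > rule$threshold,
    lt = m < rule$threshold,
    abort(sprintf("unknown comparator '%s'", rule$comparator))
  )
  as.integer(hit)
}

#' Join exhaust vectors with assessment labels and demographics
#'
#' Builds the analysis dataset for one assessment: every participant with
#' at least one record of the assessment contributes all their bi-weekly
#' segments, labelled with the participant-level dichotomized mean score
#' (so all segments of a participant share one label). Each segment is
#' additionally annotated with its temporally closest assessment record
#' (ties broken toward the earlier record) for auxiliary use. Participants
#' without any record of the assessment are dropped with a message.
#'
#' @param vectors An `exhaust_tbl` from [build_exhaust()] (multiple
#'   participants allowed).
#' @param assessments Tibble `participant_id, assessment, date, score`.
#' @param rule One row of [cutoff_rules()] (selects the assessment).
#' @param demographics Optional tibble `participant_id, age, sex, cohort`;
#'   when given, `age`, `sex` (0 = F, 1 = M) and `cohort` become
#'   demographic features.
#' @param segment_origin Date of each participant's first recorded day is
#'   taken from attribute data when present; segment midpoints for
#'   nearest-assessment matching are computed from `start_date` columns if
#'   available, else from segment indices relative to the earliest
#'   assessment date.
#' @return A `coa_dataset` tibble: `participant_id`, `segment_index`,
#'   `label`, `matched_date`, `matched_score`, then feature columns.
#'   Attributes: `feature_cols`, `feature_sources` (with `demographics`
#'   entries), `assessment`.
#' @export
match_labels <- function(vectors, assessments, rule, demographics = NULL,
                         segment_origin = NULL) {
  a <- assessments[assessments$assessment == rule$assessment, , drop = FALSE]
  if (nrow(a) == 0L) abort(sprintf("no '%s' records in assessments", rule$assessment))
  feat_src <- feature_sources(vectors)
  feat_cols <- names(feat_src)

  keep_ids <- intersect(unique(vectors$participant_id), unique(a$participant_id))
  dropped <- setdiff(unique(vectors$participant_id), keep_ids)
  if (length(dropped) > 0) {
    inform(sprintf(
      "dropping %d participant(s) without %s records", length(dropped), rule$assessment
    ))
  }
  v <- vectors[vectors$participant_id %in% keep_ids, , drop = FALSE]

  labels <- vapply(keep_ids, function(pid) {
    dichotomize(a$score[a$participant_id == pid], rule)
  }, integer(1))

  # nearest assessment per segment (segment midpoint = origin + 14*idx + 7)
  origin_of <- segment_origin %||% setNames(
    rep(min(a$date), length(keep_ids)), keep_ids
  )
  mid <- as.Date(origin_of[v$participant_id]) + 14L * v$segment_index + 7L
  matched_date <- as.Date(rep(NA, nrow(v)))
  matched_score <- rep(NA_real_, nrow(v))
  for (i in seq_len(nrow(v))) {
    ai <- a[a$participant_id == v$participant_id[i], ]
    dist <- abs(as.numeric(ai$date - mid[i]))
    j <- which(dist == min(dist))
    if (length(j) > 1) j <- j[which.min(as.numeric(ai$date[j]))]
    matched_date[i] <- ai$date[j]
    matched_score[i] <- ai$score[j]
  }

  out <- dplyr::bind_cols(
    tibble(
      participant_id = v$participant_id,
      segment_index = v$segment_index,
      label = labels[v$participant_id],
      matched_date = matched_date,
      matched_score = matched_score
    ),
    v[, feat_cols, drop = FALSE]
  )
  if (!is.null(demographics)) {
    d <- demographics
    d$sex <- as.numeric(d$sex == "M")
    out <- left_join(out, d[, c("participant_id", "age", "sex", "cohort")], by = "participant_id")
    feat_src <- c(feat_src, setNames(rep("demographics", 3), c("age", "sex", "cohort")))
    feat_cols <- c(feat_cols, c("age", "sex", "cohort"))
  }
  structure(out,
    feature_cols = feat_cols, feature_sources = feat_src,
    assessment = rule$assessment,
    class = c("coa_dataset", class(out))
  )
}

#' Drop bi-weekly segments with too much missingness per sensor system
#'
#' Two rule variants are supported: `"per_system_missing"` (default) keeps
#' a segment when the fraction of missing measures within each sensor
#' system's feature block is below `max_missing_frac`; `"per_system_valid"`
#' keeps it when at least `max_missing_frac` of each block's measures are
#' valid (a much weaker condition).
#'
#' @param dataset A `coa_dataset` (or `exhaust_tbl`).
#' @param max_missing_frac Threshold fraction (default 0.30).
#' @param variant Rule reading, see above.
#' @return Filtered dataset of the same class.
#' @export
filter_valid_segments <- function(dataset, max_missing_frac = 0.30,
                                  variant = c("per_system_missing", "per_system_valid")) {
  variant <- match.arg(variant)
  src <- feature_sources(dataset)
  keep_rows <- rep(TRUE, nrow(dataset))
  for (system in c("pir_door", "bed")) {
    cols <- names(src)[src == system]
    if (length(cols) == 0L) next
    frac_missing <- rowMeans(is.na(as.matrix(dataset[, cols, drop = FALSE])))
    keep_rows <- keep_rows & if (variant == "per_system_missing") {
      frac_missing < max_missing_frac
    } else {
      (1 - frac_missing) >= max_missing_frac
    }
  }
  out <- dataset[keep_rows, , drop = FALSE]
  attributes(out)[c("feature_cols", "feature_sources", "assessment")] <-
    attributes(dataset)[c("feature_cols", "feature_sources", "assessment")]
  class(out) <- class(dataset)
  out
}

#' Screen digital measures for cohort bias
#'
#' Measures that almost perfectly separate the recruitment cohorts would
#' let a classifier exploit recruitment artifacts rather than physiology.
#' For each measure the single-feature ranking AUC for cohort membership
#' is computed (missing values excluded, orientation-free:
#' `max(auc, 1 - auc)`); measures at or above `auc_threshold` are flagged.
#' A manual exclusion list is honoured regardless of AUC.
#'
#' @param dataset A `coa_dataset` with demographics joined (needs
#'   `cohort`).
#' @param demographics Optional demographics tibble if `cohort` is not a
#'   column of `dataset`.
#' @param auc_threshold Flagging threshold (default 0.95).
#' @param manual_exclude Character vector of measure ids always flagged.
#' @return Tibble `measure_id, cohort_auc, flagged, reason`.
#' @export
screen_cohort_bias <- function(dataset, demographics = NULL, auc_threshold = 0.95,
                               manual_exclude = character()) {
  cohort <- if ("cohort" %in% names(dataset)) {
    dataset$cohort
  } else if (!is.null(demographics)) {
    demographics$cohort[match(dataset$participant_id, demographics$participant_id)]
  } else {
    abort("cohort information required (join demographics first)")
  }
  feat_cols <- setdiff(
    attr(dataset, "feature_cols") %||% names(feature_sources(dataset)),
    c("age", "sex", "cohort")
  )
  if (length(unique(cohort[!is.na(cohort)])) < 2) {
    warn("single cohort present; no bias screening possible")
    return(tibble(
      measure_id = manual_exclude, cohort_auc = NA_real_,
      flagged = rep(TRUE, length(manual_exclude)),
      reason = rep("manual", length(manual_exclude))
    ))
  }
  y <- as.integer(cohort == max(cohort, na.rm = TRUE))
  rows <- lapply(feat_cols, function(m) {
    x <- dataset[[m]]
    ok <- !is.na(x) & !is.na(y)
    auc <- if (sum(y[ok] == 1) > 0 && sum(y[ok] == 0) > 0) {
      a <- rank_auc(y[ok], x[ok])
      max(a, 1 - a)
    } else {
      NA_real_
    }
    tibble(
      measure_id = m, cohort_auc = auc,
      flagged = (is.finite(auc) && auc >= auc_threshold) || m %in% manual_exclude,
      reason = if (m %in% manual_exclude) "manual" else if (is.finite(auc) && auc >= auc_threshold) "auc" else ""
    )
  })
  bind_rows(rows)
}

#' Remove feature columns from a dataset
#'
#' @param dataset A `coa_dataset`.
#' @param measure_ids Feature columns to drop.
#' @return Dataset without those features (attributes updated).
#' @export
exclude_measures <- function(dataset, measure_ids) {
  drop <- intersect(measure_ids, names(dataset))
  out <- dataset[, setdiff(names(dataset), drop), drop = FALSE]
  fc <- setdiff(attr(dataset, "feature_cols"), measure_ids)
  fs <- feature_sources(dataset)
  fs <- fs[setdiff(names(fs), measure_ids)]
  attr(out, "feature_cols") <- fc
  attr(out, "feature_sources") <- fs
  attr(out, "assessment") <- attr(dataset, "assessment")
  class(out) <- class(dataset)
  out
}
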