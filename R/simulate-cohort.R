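# Cohort-level simulation: latent severities -> routine shifts -> streams,
# plus assessment scores constructed around the clinical cut-offs and
# demographics independent of phenotype (by default).

# Score-generating distributions per assessment: means on either side of
# the cut-off; draws are truncated to the intended side so that, with zero
# label noise, dichotomization reproduces the intended label exactly.
assessment_score_model <- function() {
  tibble(
    assessment = ASSESSMENTS,
    case_mean = c(15, 15, 8, 8, 19),
    control_mean = c(9, 26, 3, 2, 27),
    sd = c(2, 2, 1.5, 2, 2),
    lo = c(0, 0, 0, 0, 0),
    hi = c(60, 28, 17, 15, 30)
  )
}

draw_assessment_score <- function(assessment, is_case, n_records = 2) {
  m <- assessment_score_model()
  m <- m[m$assessment == assessment, ]
  rule <- cutoff_rules()
  rule <- rule[rule$assessment == assessment, ]
  eps <- 0.1 # scores are reported to one decimal; keep clear of the cut-off
  # the half-line of scores consistent with the intended label
  bound <- switch(rule$comparator,
    ge = if (is_case) c(rule$threshold, m$hi) else c(m$lo, rule$threshold - eps),
    gt = if (is_case) c(rule$threshold + eps, m$hi) else c(m$lo, rule$threshold),
    lt = if (is_case) c(m$lo, rule$threshold - eps) else c(rule$threshold, m$hi)
  )
  mu <- if (is_case) m$case_mean else m$control_mean
  round(rtruncnorm1(n_records, mu, m$sd, bound[1], bound[2]), 1)
}

#' Simulate a labelled synthetic cohort
#'
#' Draws per-participant case status for each requested assessment (cases
#' `round(n * case_fraction)`, assigned at random), latent severities
#' (cases near 1, controls near 0), maps severity through the phenotype
#' effect table into routine shifts, generates each participant's streams
#' with [simulate_participant()], applies outages, and emits assessment
#' scores whose dichotomization by the standard cut-offs reproduces the
#' intended labels (up to `label_noise`), plus demographics drawn
#' independently of phenotype.
#'
#' @param n Number of participants (>= 2).
#' @param case_fraction Named vector over assessments, e.g.
#'   `c(MoCA = 0.5)`; assessments not listed get no cases and no effects.
#' @param days Recording length per participant.
#' @param outages [outage_model()] applied to every recording.
#' @param seed Integer master seed; everything downstream is reproducible.
#' @param routine Baseline [routine_params()] shared by the cohort.
#' @param effects Phenotype effect table (see [phenotype_spec()]); pass a
#'   zero-value table for a null cohort.
#' @param label_noise Probability that a participant's scores are drawn on
#'   the wrong side of the cut-off.
#' @param transform Optional function applied to each recording right
#'   after generation (e.g. [digital_exhaust()]); its results replace the
#'   recordings in the output, which keeps cohort-scale memory flat.
#' @param timezone,start_date Recording identity defaults.
#' @return List with elements `recordings` (list, one per participant, of
#'   recordings or `transform` results), `assessments`
#'   (`participant_id, assessment, date, score`), `demographics`
#'   (`participant_id, age, sex, cohort`) and `labels`
#'   (`participant_id, assessment, intended_label, severity`).
#' @export
simulate_cohort <- function(n, case_fraction = c(MoCA = 0.5), days = 180,
                            outages = outage_model(0), seed = 1,
                            routine = routine_params(),
                            effects = default_phenotype_effects(),
                            label_noise = 0, transform = NULL,
                            timezone = "UTC", start_date = as.Date("2021-03-01")) {
  if (n < 2) abort("n must be >= 2")
  if (any(case_fraction < 0 | case_fraction > 1)) abort("case fractions must lie in [0, 1]")
  bad <- setdiff(names(case_fraction), ASSESSMENTS)
  if (length(bad) > 0) abort(sprintf("unknown assessment(s): %s", paste(bad, collapse = ", ")))

  plan <- with_local_seed(seed, {
    ids <- sprintf("sim-%03d", seq_len(n))
    lab <- list()
    sev <- matrix(0, n, length(ASSESSMENTS), dimnames = list(ids, ASSESSMENTS))
    for (a in names(case_fraction)) {
      n_case <- round(case_fraction[[a]] * n)
      case_ids <- sample(ids, n_case)
      is_case <- ids %in% case_ids
      sev[, a] <- ifelse(is_case, runif(n, 0.7, 0.95), runif(n, 0.05, 0.25))
      lab[[a]] <- tibble(
        participant_id = ids, assessment = a,
        intended_label = as.integer(is_case), severity = sev[, a]
      )
    }
    flip <- if (label_noise > 0) {
      matrix(runif(n * length(case_fraction)) < label_noise,
        n,
        dimnames = list(ids, names(case_fraction))
      )
    } else {
      matrix(FALSE, n, length(case_fraction), dimnames = list(ids, names(case_fraction)))
    }
    list(
      ids = ids, sev = sev, labels = bind_rows(lab), flip = flip,
      part_seeds = sample.int(.Machine$integer.max, n),
      demo_seed = sample.int(.Machine$integer.max, 1),
      score_seed = sample.int(.Machine$integer.max, 1)
    )
  })

  recordings <- vector("list", n)
  names(recordings) <- plan$ids
  for (i in seq_len(n)) {
    ph <- phenotype_spec(plan$sev[i, ], effects = effects)
    rec <- simulate_participant(routine, ph,
      days = days, seed = plan$part_seeds[i],
      participant_id = plan$ids[i], timezone = timezone, start_date = start_date
    )
    if (outages$rate_per_month > 0) {
      rec <- inject_missingness(rec, outages, seed = plan$part_seeds[i] %% 1000003L)
    }
    recordings[[i]] <- if (is.null(transform)) rec else transform(rec)
  }

  assessments <- with_local_seed(plan$score_seed, {
    rows <- list()
    for (a in names(case_fraction)) {
      lab_a <- plan$labels[plan$labels$assessment == a, ]
      for (i in seq_len(n)) {
        is_case <- lab_a$intended_label[i] == 1L
        if (plan$flip[i, a]) is_case <- !is_case
        sc <- draw_assessment_score(a, is_case, n_records = 2)
        rows[[length(rows) + 1L]] <- tibble(
          participant_id = plan$ids[i], assessment = a,
          date = start_date + c(30L, days - 30L), score = sc
        )
      }
    }
    bind_rows(rows)
  })

  demographics <- with_local_seed(plan$demo_seed, tibble(
    participant_id = plan$ids,
    age = round(rtruncnorm1(n, 85, 6, 70, 100)),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.67, 0.33)),
    cohort = sample(1:2, n, replace = TRUE)
  ))

  list(
    recordings = recordings, assessments = assessments,
    demographics = demographics, labels = plan$labels
  )
}

#' Zero-effect phenotype table (null cohort)
#'
#' @return The default effect table with all values set to 0; severities
#'   then have no influence on behaviour, giving a null cohort for
#'   calibration checks.
#' @export
null_phenotype_effects <- function() {
  e <- default_phenotype_effects()
  e$value <- 0
  e
}
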