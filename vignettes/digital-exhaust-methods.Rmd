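---
title: "Methods: from contactless home sensing to digital clinical outcome assessments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from contactless home sensing to digital clinical outcome assessments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`dexhaust` turns the raw streams of a zero-interaction home-monitoring
installation — room-level passive-infrared (PIR) motion sensors sampled at
0.5 Hz, reed-switch contacts on the entrance and fridge doors, and an
under-mattress bed sensor reporting heart rate, respiration rate, in-bed
movement and sleep stages at 0.25 Hz — into a *digital exhaust*: a large,
systematically derived vector of digital measures per participant and
bi-weekly period. On top of that exhaust it builds machine-learning digital
clinical outcome assessments (COAs) for fall risk, frailty, late-life
depression and mild cognitive impairment, and ranks individual measures as
digital-biomarker candidates via SHAP attributions.

The pipeline has four stages:

1. **Daily/nightly base measures.** Each calendar day (local midnight to
   midnight, half-open) and each anchored night yields one value per base
   measure: room activity and transitions, outings and fridge use, door-use
   clock times, sleep architecture, bed exits and toss-turns, nocturnal
   heart-rate summaries including a dipping index, respiration, and Welch
   band-power/entropy measures of the nightly channels.
2. **Bi-weekly aggregation.** Non-overlapping 14-day segments, aligned to
   each participant's first recorded day, summarize every base measure with
   the statistic set q10/q25/q50/q75/q90, iqr, mean, coefficient of
   variation and the quantile-based robust skewness/kurtosis `sk3`/`kr3`
   (Kim–White naming). Rhythmicity measures (cosinor) are fitted on the raw
   bi-weekly signal directly. A measure with fewer than 10 valid days in a
   segment is missing — explicitly, never imputed.
3. **Digital COAs.** Exhaust vectors are joined to demographics and to a
   dichotomized clinical label (TUG ≥ 12 s, POMA < 19, EFS > 5, GDS ≥ 5,
   MoCA < 23; multiple scores averaged first). Evaluation uses repeated
   70/30 participant-level label-stratified splits, per-iteration random
   hyperparameter search with inner stratified 3-fold cross-validation,
   XGBoost (native missing-value handling), participant-level soft voting,
   and ROC AUC / PrAUC.
4. **Explanation.** Per-iteration exact TreeSHAP matrices are aggregated
   into a global importance per measure (sum over iterations of the mean
   absolute SHAP value) with dense ranking; a single full-data model with
   fixed mid-range hyperparameters supplies beeswarm-style per-sample
   values, deliberately kept distinct from the resampled global ranking.

# Calendar conventions

Days are local-midnight to local-midnight in the apartment's IANA
timezone; daylight-saving days are 23 or 25 h long and are accepted. All
windows are half-open `[start, end)` so no epoch is counted twice. Nights
are anchored noon-to-noon: a night starting after 12:00 belongs to that
evening's date, a night starting after midnight to the previous date. If
several in-bed periods anchor to one date, the longest is the date's main
night and the rest are treated as naps and excluded. These are standard
actigraphy conventions; they are configurable where reasonable people
differ.

Day-validity defaults: the PIR/door system is valid on a day when the
union of room reporting covers ≥ 20 h and at least one on/off state change
occurred; the bed system is valid when the anchored main night carries
≥ 3 h of non-missing stage samples. These thresholds are deliberate,
exposed parameters (`min_pir_coverage_h`, `min_stage_h`): published
deployments differ in their inclusion rules, so the package treats them as
policy, not constants.

# Statistical layer

* **Quantiles** use linear interpolation between closest order statistics
  (`stats::quantile` type 7), pinned so results are bit-stable.
* **coefvar** is the sample SD (n−1) over the mean, missing when
  |mean| < 1e−12.
* **sk3** is the Groeneveld–Meeden form `(mean − median) / mean|x − median|`.
  A constant sample is symmetric, so sk3 is defined as 0 there rather than
  missing; otherwise a vanishing denominator yields missing.
* **kr3** is the Hogg form `(U_0.05 − L_0.05)/(U_0.5 − L_0.5) − c` with
  tail means taken over fractional order-statistic counts. The centering
  constant defaults to `c = 2.59`, which we verified analytically for the
  normal distribution: `2·φ(z_0.95)/0.05 / (2·φ(0)) ≈ 2.585`. kr3 requires
  ≥ 20 present values for stability; since a bi-weekly segment holds at
  most 14 daily values, kr3 derivates are structurally missing at daily
  granularity. They are kept in the default statistic set for fidelity to
  the naming convention — the classifier's native missing handling makes
  them inert — and the statistic set is configurable if a user prefers to
  drop them.
* **Cosinor.** `y(t) = M + A·cos(2πt/P − φ)` is fitted by the standard
  linearization on 10-min binned activity, with `t = 0` at local midnight
  so the acrophase is a clock time. Bin timestamps use the mean sample
  time within each bin, which makes noiseless recovery exact. A
  zero-variance signal returns amplitude 0, missing acrophase, R² 0.
* **Spectral measures.** Welch averaged periodograms (Hann window, 256
  samples, 50% overlap) over the 0.25 Hz nightly channels; gaps ≤ 60 s are
  linearly interpolated and longer gaps split the signal. Band powers are
  reported as fractions of total non-DC power over the default bands
  (0–0.01], (0.01–0.04], (0.04–0.125] Hz, plus normalized spectral entropy
  and total power. The band edges are configuration, not dogma: they
  partition the available band below the 0.125 Hz Nyquist limit into
  slow/medium/fast variability.

# The heart-rate dipping proxy

A bed sensor records no daytime heart rate, so the classical day/night
dipping ratio cannot be formed. The package uses a within-night proxy:
`hr_dipping = (B − T)/B`, where `B` is the mean heart rate over the first
30 min in bed and `T` the minimum 10-min rolling mean across the night.
Both windows are parameters. On simulated nights with a known dip
fraction, the pipeline recovers the injected value to within 0.02.

# Base-measure registry

Every emitted measure is declared in a registry (`measure_registry()`)
carrying id, source system, granularity, unit and a one-line hypothesis.
The built-in set (53 daily/nightly measures + 4 per-segment cosinor
parameters, i.e. 534 derived columns under the default statistic set)
covers each family of the extraction architecture: activity volume and
location, in-home transitions, fragmentation and room entropy, outings,
fridge use, door-use timing, sleep architecture, bed exits, toss-turns,
in-bed activity, nocturnal cardiorespiratory summaries including dipping,
spectral measures, and cosinor rhythmicity. It is intentionally a
*representative* catalogue with an extension point (`register_measure()`):
user extractors gate on the same validity rules and flow into the exhaust
unchanged. Two definitional choices that the measure names leave open are
fixed here: `tod_middle` is the *median* event time (robust to a single
late event), and `activity_fragmentation` divides the union signal's
active/inactive alternation count by total active minutes, making the
index duration-invariant.

# Synthetic cohort

The simulator exists so that every stage is testable without clinical
data, and it defines the package's study conditions:

* **Occupancy** is a semi-Markov process over six rooms; dwell times are
  exponential with room-specific means rescaled so the expected number of
  room changes matches `transition_rate` (default 60/day). Within a dwell,
  PIR activity alternates active/inactive bouts with ~0.4 duty cycle; all
  runs land on the 2-s grid, and rooms report off-states continuously so
  coverage is complete unless an outage is injected.
* **Outings** are door-event pairs bracketing interior silence
  (default 1.5/day, mean 90 min); fridge events (default 6/day) pause
  while the resident is out, so door streams alternate cleanly.
* **Nights** (default onset 22:45 ± 0.6 h, 8 ± 0.6 h in bed) carry heart
  rate as a baseline (65 bpm) dipping by a per-night fraction drawn from a
  truncated normal (mean 0.12, SD 0.04), with AR(1) noise (coefficient 0.9
  at 4-s steps — slow physiological wander); stage bouts follow a
  row-stochastic transition matrix; toss-turns and bed exits are Poisson,
  and bed exits force awake stages and bathroom PIR activity.
* **Phenotypes.** Latent per-assessment severities in [0, 1] shift routine
  parameters along the qualitative directions associated with each
  outcome (frailty: fewer fridge openings, fewer transitions, longer
  sleep; fall risk: more in-bed movement and bed exits; depression: longer
  sleep, fewer outings; cognitive impairment: higher night-to-night
  dipping variability and more irregular sleep timing). Magnitudes are
  configuration; the defaults are strong enough for closed-loop recovery
  and a zero-effect table (`null_phenotype_effects()`) gives a null
  cohort.
* **Assessment scores** are drawn on the intended side of each cut-off
  (truncated normals with means well separated from the threshold), so
  dichotomization reproduces intended labels exactly at zero label noise;
  a label-noise probability flips sides. Demographics are drawn
  independently of phenotype by default, which is what makes the
  demographics-only scenario an honest baseline.

What the simulator does *not* emulate: multi-resident homes, pets, sensor
physics (IR optics, piezo mechanics), raw high-frequency bed-sensor bands,
visitor traffic, or correlated day-to-day behavioural drift. Passing
closed-loop tests therefore demonstrates that the pipeline recovers known
signal under its own generative assumptions — not that real cohorts are
this separable. On real data the exhaust-vs-demographics gap will be
smaller and missingness patterns more adversarial.

# Evaluation design

Segments are the training rows (a participant's label is broadcast to all
their segments); participants are the unit of splitting, so no participant
contributes to both train and test — asserted programmatically in every
iteration. Inner model selection maximizes segment-level ROC AUC via
stratified 3-fold CV over training participants with random search. The
default search space is sized for tens of participants: 50–250 trees,
depth 2–6, learning rate log-uniform [0.03, 0.3], subsample [0.5, 1],
column subsample [0.3, 1], min child weight 1–10, with coarse histogram
binning (`max_bin = 16`). At a few hundred rows, larger/deeper spaces only
add variance and tuning cost; the sampler is replaceable via
`config_sampler` for users with bigger cohorts. Iteration summaries are
reported as mean ± normal-approximation 95% CI half-width (a percentile
option exists, since the presentation convention does not determine the
interval type).

Segment-validity filtering defaults to the stricter reading of the
two-sensor-system rule — a segment is kept when the missing fraction
*within each system's feature block* is below 30% — because the weaker
"≥ 30% valid" reading keeps segments that are 70% missing; both variants
are implemented (`filter_valid_segments(variant=)`). Measures that nearly
separate recruitment cohorts (single-feature AUC ≥ 0.95) can be screened
out, alongside a manual exclusion list, mirroring the practice of removing
recruitment artifacts while keeping cohort membership available to the
model as an explicit demographic feature.

# Problem sizes used in the shipped checks

The automated checks run a 40-participant, 180-day cohort with strong
cognitive-impairment effects through the full loop (exhaust extraction,
MoCA labelling, 20 evaluation iterations with 10 search trials), alongside
statistic-oracle suites at n = 10⁵ and 1,000-vector brute-force
comparisons. These sizes were chosen as the smallest at which the
stochastic claims (AUC separation, null calibration, tail-statistic
calibration) are stable across seeds; all of them are parameters, and
nothing in the package caps larger runs.

# Known limitations

* Multi-resident disambiguation is out of scope; measures assume a
  single-occupant home.
* The raw 50/100 Hz bed-sensor bands are not processed; the package starts
  from the device's derived channels.
* Cross-sectional design: segments inherit a participant-level label;
  trajectory modelling over segments is future work.
* SHAP importances are associations under the fitted model, not causal
  claims.
* kr3 at daily granularity is structurally missing (see above); it becomes
  informative only for sub-daily base measures or longer aggregation
  windows.
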