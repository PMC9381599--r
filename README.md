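# dexhaust

Long-term remote monitoring of older adults increasingly relies on
*zero-interaction* sensing: devices that require no wearing, charging or
input. A typical installation has passive-infrared (PIR) motion sensors in
the essential rooms (0.5 Hz on/off activity), reed-switch contacts on the
entrance and fridge doors, and an under-mattress bed sensor reporting
nocturnal heart rate, respiration, in-bed movement and sleep stages at
0.25 Hz. `dexhaust` is for researchers who want to turn those streams into
a **digital exhaust** — a comprehensive, systematically derived vector of
digital measures per bi-weekly period — and to evaluate machine-learning
**digital clinical outcome assessments** (COAs) and digital-biomarker
candidates on top of it.

## What it computes

* **Daily/nightly base measures** from a pluggable registry: per-room
  activity minutes, room transitions and entropy, activity fragmentation,
  outings (entrance-door events bracketing interior silence), fridge use,
  door-use clock times, sleep duration/efficiency/architecture, bed exits,
  toss-turns, in-bed activity, nocturnal heart-rate summaries including a
  within-night dipping index (B − T)/B, respiration, and Welch band-power
  and spectral-entropy measures.
* **Bi-weekly exhaust vectors**: non-overlapping 14-day segments
  summarized with q10/q25/q50/q75/q90, iqr, mean, coefvar and the
  Kim–White robust skewness/kurtosis (sk3 = (mean − median)/mean|x − median|;
  kr3 = (U₀.₀₅ − L₀.₀₅)/(U₀.₅ − L₀.₅) − 2.59), plus per-segment cosinor
  rhythm parameters y(t) = M + A·cos(2πt/24 − φ). Measures with fewer than
  10 valid days in a segment are missing, never imputed.
* **Digital COAs**: exhaust + demographics joined to dichotomized clinical
  labels (TUG ≥ 12 s, POMA < 19, EFS > 5, GDS ≥ 5, MoCA < 23), evaluated
  by repeated participant-stratified 70/30 splits with inner 3-fold CV and
  random search over an XGBoost space, participant-level soft voting, and
  ROC AUC / PrAUC with 95% CIs.
* **Biomarker ranking**: global SHAP importance per measure,
  SHAPᵍˡᵒᵇᵃˡ_m = Σᵢ mean(|SHAPᵢ_m|) over simulation iterations, plus
  beeswarm and group-averaged z-normalised heatmap exports.
* **A synthetic cohort simulator** (semi-Markov room occupancy, door
  events consistent with outings, full night records with AR(1) heart-rate
  noise and phenotype-linked effects) so the entire pipeline is testable
  without access to clinical data.

## Worked example

```r
library(dexhaust)

rec <- simulate_participant(routine_params(), days = 45, seed = 7,
                            participant_id = "demo-01")
rec
#> <home_recording> participant demo-01 (UTC)
#>   PIR runs: 29058 across 6 rooms
#>   door events: 836
#>   nights: 45

ex <- digital_exhaust(rec)   # 3 bi-weekly segments x 534 derived measures
dplyr::select(ex, segment_index, mean_total_activity, q50_sleep_duration,
              mean_hr_dipping, cosinor_acrophase)
#> # A tibble: 3 x 5
#>   segment_index mean_total_activity q50_sleep_duration mean_hr_dipping
#>           <int>               <dbl>              <dbl>           <dbl>
#> 1             0                331.               7.84           0.131
#> 2             1                338.               7.90           0.127
#> 3             2                356.               7.36           0.127
```

`mean_total_activity` is the segment mean of daily PIR activity minutes
(~5.5 h/day of detected movement), `q50_sleep_duration` the median nightly
hours asleep, `mean_hr_dipping` the average within-night heart-rate dip
(close to the simulator's injected 12%), and `cosinor_acrophase` the clock
time of the fitted daily activity peak:

```r
fit <- fit_cosinor(dexhaust:::pir_activity_signal(
  rec, as.POSIXct("2021-03-01", tz = "UTC"), as.POSIXct("2021-03-15", tz = "UTC")))
fit
#> <cosinor_fit> mesor 2.298, amplitude 1.624, acrophase 15.14 h, R^2 0.236 (14 days, 2016 bins)
```

A full COA evaluation on a simulated cohort:

```r
sim <- simulate_cohort(n = 40, case_fraction = c(MoCA = 0.5), days = 180,
                       seed = 1, transform = digital_exhaust)
ex  <- dplyr::bind_rows(sim$recordings)
attr(ex, "feature_sources") <- feature_sources(sim$recordings[[1]])

rule <- dplyr::filter(cutoff_rules(), assessment == "MoCA")
ds <- match_labels(ex, sim$assessments, rule, demographics = sim$demographics) |>
  filter_valid_segments()

res <- run_simulation(ds, "exhaust", n_iterations = 20, search_trials = 10, seed = 11)
glance(res)                       # mean ROC AUC / PrAUC with 95% CI half-widths
global_shap(res$shap)             # ranked digital-biomarker candidates
```

## Command line

A thin CLI over the same functions lives at `inst/scripts/exhaust.R`:

```sh
Rscript inst/scripts/exhaust.R simulate --out cohort/ --n 4 --days 30 --seed 1
Rscript inst/scripts/exhaust.R validate cohort/
Rscript inst/scripts/exhaust.R extract --dir cohort/ --id sim-001 --out sim-001_exhaust.csv
```

## Scope notes

Single-occupant homes only (multi-resident disambiguation is out of
scope); the raw 50/100 Hz bed-sensor bands are not processed; SHAP
rankings are associations under the fitted model, not causal claims. See
`vignettes/digital-exhaust-methods.Rmd` for the full methods account.
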