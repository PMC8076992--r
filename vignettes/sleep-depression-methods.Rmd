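---
title: "Methods: wearable sleep features and depression severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable sleep features and depression severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Consumer wearables stage sleep each night into awake, light, deep and
REM segments. In longitudinal mental-health cohorts these hypnograms
arrive alongside biweekly PHQ-8 depression questionnaires (8 items
scored 0-3; the total, 0-24, summarizes depressive symptom severity
over the past two weeks, and item 3 - "trouble falling or staying
asleep, or sleeping too much" - is a self-reported sleep subscore).
`sleepdep` turns raw stage-segment sessions into 18 interpretable sleep
features per questionnaire and estimates how each feature moves with
depression severity across a multi-site cohort, while a synthetic
cohort generator with known couplings makes the whole chain testable.

## From sessions to nights

A *session* is a contiguous run of stage segments. Three conventions
map sessions to analysable nights; none of them is dictated by the
data format, so each is an explicit design choice:

* **Noon rule.** A session is attributed to the calendar evening it
  began: start at or after 12:00 means the session's own date,
  earlier means the previous date. This is the standard actigraphy
  convention and handles after-midnight bedtimes.
* **Main sleep.** When several sessions share an anchor date (naps,
  split recordings), the one with the largest time in bed wins; ties
  go to the earlier start. Discarded sessions are logged, never
  silently dropped.
* **Linear clock axis.** Onset and offset are stored as hours since
  midnight *of the anchor date*, so 23:30 is 23.5 and 04:30 the next
  morning is 28.5. Means and standard deviations across midnight are
  then ordinary arithmetic; no circular statistics are needed. Times
  can be taken modulo 24 for display.

Per night we compute: total sleep time (TST; light + deep + REM), time
in bed (TIB; all stages, awake included), per-stage minutes, onset
(start of the first non-awake segment), offset (end of the last),
REM latency (onset to the first REM segment; missing when the night
never reaches REM), sleep efficiency (100·TST/TIB), and awakening
counts. Awake episodes are counted only *strictly between* onset and
offset: awake time before onset is sleep-onset latency and awake time
after offset is terminal wakefulness, and neither is an "awakening".
Thresholds are read literally: an awakening counts when it is strictly
longer than 5 minutes; a *prolonged* awakening is at least 30 minutes;
a hypersomnia night has TST strictly above 10 hours; a potential
middle-insomnia night needs *both* TST under 6 hours and a prolonged
awakening. A night is a weekend night when its anchor date is a Friday
or Saturday - the sleep that precedes a non-work day.

Two invariants tie the definitions together and are enforced by tests:
per-night stage percentages (over TIB) sum to exactly 100, and
efficiency equals 100 minus the awake percentage.

## The 18 windowed features

Each PHQ-8 record is paired with the nights in the half-open window
`[date − 14, date)`: the 14 nights ending with the sleep that finished
on the questionnaire morning. The questionnaire day's own night is
excluded - it is not yet complete when the questionnaire is answered.

| Group | Features | Aggregation |
|---|---|---|
| Architecture | `Av_tst`, `Av_time_bed`, `Deep_pct`, `Light_pct`, `REM_pct`, `NREM_pct`, `Awake_pct`, `Av_onset`, `Av_offset`, `REM_L` | means of per-night values |
| Stability | `Std_tst`, `Std_onset`, `Std_offset` | sample SD (n−1), missing with < 2 nights |
| Quality | `Efficiency`, `Awake_5`, `WKD_diff` | means; `WKD_diff` = weekend − weekday mean TST |
| Insomnia | `M_insomnia` | % of window nights flagged |
| Hypersomnia | `Dur_10` | % of window nights with TST > 10 h |

Stage percentages are averaged as *per-night percentages* (mean of
ratios), not pooled minutes, so every night contributes equally
regardless of its length; this matches the features' definition as
"mean percentage of ...". `REM_L` averages only nights where REM
latency is defined. `WKD_diff` requires both a weekend and a weekday
night in the window. A record missing one of these features is
excluded from that feature's model only; the analyses are bivariate
per feature, so nothing else is lost.

## Inclusion criteria

Four rules produce the analysis set, applied in a fixed order:
record-level first - (1) complete PHQ-8 (all 8 items), (2) at least 12
nights in the 14-day window (~85% coverage), (3) completion date
before 2020-02-01 (excluding pandemic-era sleep) - then the
participant-level rule, (4) at least 3 surviving records per
participant. The participant rule runs last deliberately: "number of
records" is only meaningful if it counts records that would otherwise
be analysed. A record failing several rules is tallied under the first
failing rule, so the exclusion report sums exactly to the input size.
All boundaries are inclusive as stated (12 kept, 11 dropped; 3 kept, 2
dropped; the cutoff date itself excluded).

## Association models

For each feature and outcome (PHQ-8 total or sleep subscore) we fit a
random-intercept linear mixed model with the *sleep feature as the
response* and the depression score as the predictor:

$$
\mathrm{Sleep}_{ijk} = \delta_{000} + V_{00k} + U_{0jk}
 + \beta_1\,\mathrm{PHQ8}_{ijk} + \beta_2\,\mathrm{age}_{jk}
 + \beta_3\,\mathrm{gender}_{jk} + \beta_4\,\mathrm{education}_{jk}
 + \beta_5\,\mathrm{income}_{jk} + \varepsilon_{ijk}
$$

with participant random intercepts $U_{0jk}$ and, for the pooled
multi-site ("three-level") fit, site random intercepts $V_{00k}$;
per-site analyses use the two-level form. Choices worth stating:

* **Estimation** is restricted maximum likelihood via `lme4::lmer`.
* **Inference** on $\beta_1$ is Wald: $z = \beta_1/\mathrm{SE}$,
  two-sided p from the standard normal, CI $\beta_1 \pm 1.96\,
  \mathrm{SE}$. No Satterthwaite degrees of freedom - the z score is
  the test statistic throughout. Being asymptotic, this inference is
  slightly anti-conservative in very small cohorts; see the
  simulation-study design below.
* **Confounders** enter treatment-coded with references female /
  below_degree / lt15k; "not_mentioned" income is retained as its own
  level. A confounder that is constant in a subset (e.g. a single-site
  fit) is dropped from the design rather than producing a
  rank-deficient model.
* **Multiplicity.** Benjamini-Hochberg correction is applied across
  the family of the 18 features of one outcome on one dataset,
  mirroring a per-table analysis; the corrected significance level is
  0.05.
* **Box-Cox fallback.** Residual normality was historically judged
  from histograms and Q-Q plots; automation needs a numeric trigger,
  so with `boxcox = "auto"` the response is Box-Cox-transformed and
  refit when the absolute skewness of the residuals exceeds 1. Lambda
  maximizes the profile log-likelihood on the grid [−2, 2] in steps of
  0.01; non-positive responses are shifted by `1 − min(y)` first and
  the shift is reported.
* **Degenerate inputs.** A constant feature is an error naming the
  feature. With one record per participant the random-intercept
  variance is driven to the boundary and the slope equals the pooled
  OLS slope (tested to 1e-4); on noise-free linear data the exact
  slope is recovered.

Spearman correlations between the PHQ-8 total and the sleep subscore
(overall and per site) use mid-ranks for ties, the large-sample normal
test $z = \operatorname{atanh}(r)\sqrt{n-3}$, and a Fisher-transform
95% CI.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a multi-site wearable
cohort: three sites by default with baseline PHQ-8 locations 6, 10 and
5 (the second site plays the clinical population with higher
severity), participant intercepts (SD 4), and biweekly severity
following a stationary AR(1) (marginal SD 2, correlation 0.8), clipped
to the 0-24 range. The PHQ-8 total is the rounded severity; item 3 is
a noisy, bounded function of a severity-proportional sleep-disturbance
index (noise SD 0.55, a value that produces subscore-total rank
correlations around 0.7, the strength typically reported); the other
seven items share the remaining total through a multinomial spread
with deterministic overflow repair, so items are always in 0-3 and sum
exactly to the total.

Nightly targets are linear in the severity governing the night's
feature window: baseline TST 430 min (night SD 40, participant SD 25),
awake percentage 7% (SD 2.5 / 1.5), onset 23:15 (SD 0.7 h / 0.5 h).
Couplings are per PHQ-8 point on the feature's own scale and default
to zero; the acceptance analyses inject `awake_pct = 0.035` percentage
points per point - the magnitude reported for this feature in
wearable-cohort studies - plus small TST/onset couplings and
log-odds couplings for prolonged awakenings and hypersomnia nights
(0.12/point on baseline probabilities 0.12 and 0.015). Because offset
is onset plus time in bed, an independent offset coupling is
geometrically impossible; the emergent offset coupling is positive, as
published. All randomness flows from one seed; identical seeds give
byte-identical cohorts.

Targets are realized as segments by a deterministic plan: stage
minutes are the largest-remainder (Hamilton) allocation of
`frac × TST` - so stage minutes always sum exactly to TST - split
evenly across ~90-minute cycles, light → deep → REM within each cycle,
with the first REM block placed in cycle 1 or 2 (probability 0.35 for
cycle 2), which controls REM latency. Awakening episodes are inserted
at cycle boundaries strictly inside the sleep period. The cycle
scaffold is cosmetic for every aggregate metric except REM latency,
which is why the generator also offers `realize = "nights"`: the night
records implied by the targets are computed through the same plan
arithmetic without building timestamps, and a test verifies the two
routes agree metric for metric. The simulation studies use the fast
route.

What the generator does *not* emulate: ultradian dynamics beyond the
fixed cycle scaffold, circadian light effects, device staging error,
informative missingness (nights and questionnaires are dropped
completely at random, 8% and 10% by default), and
confounder-severity associations (demographics are independent of
severity, so confounder adjustment is exercised but never load-bearing).
Passing tests therefore demonstrate that the pipeline recovers what it
is pointed at under clean longitudinal structure - not that Fitbit
staging is accurate or that real missingness is ignorable.

## Simulation-study design

* **Parameter recovery** (`run_recovery_study()`): 200 replicate
  cohorts of 201 participants (3 × 67) with 8 biweekly records each, no
  missingness, injected `Awake_pct` coupling 0.035. Checked: mean
  estimate within 10% of truth and empirical 95% CI coverage in
  [0.92, 0.98].
* **Null calibration** (`run_null_calibration()`): 100 replicate
  cohorts with every coupling zero; per replicate all 18 feature
  models are fit and BH-corrected, and we record whether any feature
  is declared significant. The study runs at 90 participants
  (3 × 30) × 8 records: large enough that the asymptotic Wald z is in
  its operating regime. We note openly that at roughly half that size
  the normal approximation is visibly anti-conservative - a property
  of z-based mixed-model inference generally, and one reason the
  per-site analyses of small sites deserve caution.
* **Synthesis round-trip**: 1,000 random target sets are synthesized
  to segments and re-scored; TST is reproduced exactly, stage minutes
  to largest-remainder precision, onset to float precision.

These scales keep the default test suite within a few minutes on one
CPU while leaving the Monte-Carlo error far below the tolerances being
checked.

## Numerical choices

* Segment contiguity tolerance is 1 second; non-contiguous sessions
  are rejected (or truncated to the longest contiguous prefix when
  repair is requested), with a logged reason.
* Stability features use the sample (n−1) standard deviation.
* Largest-remainder allocations break ties by earliest index, making
  every allocation deterministic.
* Timestamps are timezone-naive local clock time (stored as UTC);
  daylight-saving shifts are not modeled.
* Written tables carry floats at 9 significant digits so values
  round-trip within relative 1e-6; integers round-trip exactly;
  missing values are empty cells.

## Limitations

Sleep-onset latency cannot be estimated from stage data alone (the
initial awake segment is only a proxy); multiple sessions per night
are resolved by selection, not merging; features beyond the 18 (and
multi-scale windows) are out of scope, as are random slopes, joint
multivariate feature models, and predictive modelling. Associations
estimated on real data remain observational and bidirectional.
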