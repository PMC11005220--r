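---
title: "Building an energy-expenditure aging clock from metabolic-cage data"
author: "eeclock authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building an energy-expenditure aging clock from metabolic-cage data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eeclock)
```

## The problem

Whole-body energy metabolism reorganizes with age. In mice, oxygen
consumption (VO2), carbon dioxide production (VCO2) and energy
expenditure (EE) peak around 6 weeks of age and decline to roughly half
their peak by 80 weeks, while the respiratory exchange ratio
(RER = VCO2/VO2) drifts upward late in life — from about 0.75 in prime
adulthood toward 0.85 — signalling a shift in fuel utilization away from
fat oxidation. The circadian organization of metabolism degrades too:
the daily EE rhythm keeps a stable period near 1423 minutes, but its
amplitude dampens and its phase drifts.

`eeclock` turns these regularities into a quantitative **metabolic age**:
each animal's multi-channel metabolic-cage recording is reduced to 14
candidate predictors, a bagged regression-tree model learns the mapping
from predictors to chronological age on an age-ladder cohort, and the
sparse top-6 refit of that model predicts the *EE age* of new animals —
in particular of intervention arms, whose rejuvenation is read off as
the difference from aged controls.

## Data model and ingestion

A `cage_recording` is one animal's uniformly sampled multi-channel
trace (default every 18 min) plus metadata. Samples cover half-open
intervals `[t, t + dt)` and a sample's light/dark phase is decided by
its start time against a 12:12 photoperiod with lights-on at 07:00.
The standard protocol records ~120 h; the first 48 h are acclimation
and `trim_to_analysis_window()` keeps the 72 h that follow.

Where the cage software does not export EE directly, `derive_ee()`
computes it with the abbreviated Weir equation,

$$\mathrm{EE\,(kcal/h)} = \frac{3.941\,\mathrm{VO_2} + 1.106\,\mathrm{VCO_2}}{1000},$$

with VO2/VCO2 in ml/h — the standard choice for rodent indirect
calorimetry; the coefficients are an explicit, overridable argument.
RER is defined only where VO2 > 0 and left missing elsewhere.
Channels are *not* normalized to body mass: weight enters the clock as
its own predictor.

Missing-sample policy: channels with more than 5% missing samples are
rejected; smaller interior gaps are linearly interpolated **only** for
rhythm fitting and are excluded from daily means (for cumulative
channels the observed total is rescaled by the observed fraction).

## Rhythm estimation

The circadian estimand is the classical cosinor parameter set — period,
amplitude, acrophase, and MESOR (the rhythm-adjusted mean). Period
candidates are scanned on a 1-minute grid from 1200 to 1680 min
(20–28 h): for each candidate $\tau$ the power is the fraction of
variance explained by a cosine/sine pair at $\tau$, fit jointly with an
intercept by ordinary least squares. The top-k periods are the local
maxima of this curve ranked by power, ties toward the shorter period,
plateaus credited to their leftmost grid point.

Two numerical choices matter here:

* **Trend handling.** Removing a fitted line *before* the harmonic scan
  biases the peak: a 72-h window holds ~3.04 cycles of a 1423-min
  rhythm, so a separate line fit absorbs part of the cosine and shifts
  the maximum by several minutes. The scan therefore adjusts for the
  baseline (and, optionally, a linear trend) *jointly* with the
  harmonic pair, which recovers a noiseless cosine exactly and keeps
  the noisy estimator centered on the truth. On the Fourier-aligned
  subgrid the intercept-only power equals the discrete-Fourier
  variance-explained ratio to machine precision.
* **Precision limits.** With 5% AR(1) noise on a 72-h, 18-min trace the
  period estimate carries an irreducible spread of several minutes
  (the information bound for sinusoid frequency at this window length
  and signal-to-noise level), so per-trace top-1 periods scatter around
  the generating period; summaries should use the cohort median, which
  sits on the truth.

`cosinor_fit()` then estimates amplitude
$\sqrt{\beta_{\cos}^2+\beta_{\sin}^2}$, MESOR (the intercept) and the
**adjusted phase**: the fitted peak time expressed in minutes after
lights-on, wrapped to $[0, \tau)$. Lights-on is the phase reference
because it is the one schedule anchor every cage run shares; it is
configurable via the recording's `lights_on_hour`. By default all
animals are fit at the common 1423-min period — the clock's premise is
that individuals share one optimal circadian cycle — with each animal's
own top periodogram periods available as a per-animal option
(`run_trajectory(per_animal = TRUE)`).

MESOR is computed and reported but excluded from the clock's predictor
set, which uses amplitude and adjusted phase only.

## The 14-predictor feature table

`daily_means()` classifies channels by instrument semantics:
rate-like channels (VO2, VCO2, RER, EE, Speed) are averaged over all
samples; cumulative/event channels (XT, YT, Z, DistD, Drink, Feed,
SumR, SumL) are totalled per 24 h. The classification is an argument,
and the activity channels are reported as per-day totals rather than
per-hour means. `build_feature_table()` assembles, per animal:

> Weight, Adjphase, VO2, EE, RER, VCO2, Z, Feed, Amplitude, XT + YT,
> Drink, DistD, SumR + L, Speed

plus `age_weeks` and `group` labels. Light/dark-resolved summaries
(`phase_means()`) are available for reporting but are not clock
features.

## Ordination

Profiles are compared by Euclidean distance on z-scored features —
the features mix units and signed phase values, which rules out
abundance-style dissimilarities. `pcoa()` is classical scaling
(double-centering + eigendecomposition; negative eigenvalues reported,
never embedded), and `nmds()` minimizes Kruskal stress-1 with isotonic
regression on the dissimilarity ranks alternated with a Guttman update.
The update is step-halved whenever it would increase stress, so the
stress trace is non-increasing by construction; the best of 8 seeded
starts (PCoA plus 7 random) is returned. Axis signs follow a
deterministic convention (first non-zero loading positive) so repeated
runs are bit-identical.

## The clock

The construction is two-stage, on a 70/30 age-stratified split
(`split_cohort()`, exactly `floor(0.7 n)` training animals — 11/6 on a
17-animal cohort):

1. a comprehensive forest (500 trees, `mtry = floor(p/3)`, node size 5)
   on all 14 predictors of the training split ranks features by
   **IncNodePurity** — the total SSE decrease credited to splits on the
   feature over all trees;
2. the top 6 features are refit as a sparse forest whose `mtry`
   (1..6) and node size (2 or 5) are selected by 5 × 10-fold
   cross-validated RMSE on the training split (MAE and R² are recorded
   alongside), then refit on the whole training split and evaluated
   once on the held-out 30%.

Importance ties are broken by the canonical feature order, fold and
tree randomness derive from one master seed through counter-based
sub-seeding, and retraining with the same seed is bit-identical.
Intervention arms are never used in training: the clock is fit on the
untreated age ladder only, and `run_intervention_eval()` applies it to
treated groups, reporting each group's EE age (mean ± SD) and its
rejuvenation delta against the aged control group.

Hyperparameter defaults are the conventional regression-forest choices;
cross-validation picks within the small grid above. RMSE is the
selection metric because squared error is what the trees themselves
optimize.

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage can be validated against
known ground truth at desk scale. Per animal,

$$\mathrm{EE}(t) = M\left(1 + A\cos\frac{2\pi (t-\varphi)}{\tau}\right) + \varepsilon(t),$$

with mesor $M$, relative amplitude $A$ and lights-on-referenced
acrophase $\varphi$ taken from the age profile, $\tau = 1423$ min, and
$\varepsilon$ stationary AR(1) Gaussian noise (default SD 5% of $M$,
lag-1 correlation 0.3 — metabolic traces are autocorrelated, and this
level keeps period recovery non-trivial but stable). RER is generated
as its profile mean plus the same noise process scaled to the RER
level; VO2 and VCO2 are then *derived* by inverting the Weir relation,
so gas exchange, RER and EE are mutually consistent by construction.
Activity, feeding and drinking are Poisson event draws weighted 3:1
toward the dark phase (an invented but conventional event model) and
scaled by the profile's activity factor.

The default age profiles encode the study anchors: mean EE 0.50 kcal/h
at 6 weeks falling to exactly half (0.25) at 80 weeks; RER 0.75 through
56 weeks rising to 0.85 at 80; and — where no quantitative values exist
— free parameters chosen once at realistic levels and documented as
such: relative amplitude 0.30 at 6 weeks declining linearly to 0.15 at
80, acrophase delayed 60 min by 80 weeks, activity halved by 80 weeks,
food 4.0 → 3.2 g/day, water 5.0 → 4.0 ml/day, and body weight 20 → 40 g
(C57BL/6J males) with 5% between-animal scatter. Ages between anchors
interpolate linearly. An intervention arm is a pure effective-age
shift: a treated animal is generated from the profile at
`age - shift` but labeled with its chronological age, with the shift
recorded in the truth table.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: between-animal biological
heterogeneity beyond weight (every animal of a group shares one
profile, so within-group feature variance is far smaller than in real
cohorts), RER's own feeding-driven circadian structure, ultradian
activity bouts, torpor, instrument drift and missingness patterns. Two
practical consequences are worth knowing. First, clock accuracy on
synthetic ladders (test MAE well under 1 week) is an upper bound of a
different order than anything achievable on real animals. Second, a
regression forest is piecewise-constant in its training support: an
intervention arm whose effective age falls *between* ladder ages is
predicted at the nearest represented ages (e.g. an effective age of 53
weeks reads out near 56 on a {6, 20, 56, 64, 80} ladder), so recovered
rejuvenation deltas are quantized by the ladder spacing. Real studies
with denser age coverage do not share this floor.

Another finite-window subtlety: 72 h is 3.036 periods of 1423 min, so
the windowed mean of the cosine term is small but non-zero and the
time-mean of a noiseless simulated EE trace differs from $M$ by up to a
few tenths of a percent depending on phase. Trajectory ratios (the
6 → 80 week decline) are affected well below the reporting tolerance.

## Statistical reporting

`compare_groups()` implements the screen-then-test rule: Shapiro–Wilk
normality per group and Levene variance homogeneity across groups, both
at α = 0.05; if all pass, one-way ANOVA with Sidak-adjusted pairwise
comparisons (pooled-variance t statistics on the ANOVA mean square)
when there are more than two groups; otherwise Kruskal–Wallis. All
screen outcomes are reported alongside the chosen test, groups with
n < 3 or zero variance degrade to flagged descriptive entries, and no
multiplicity adjustment is applied *across* parameters (tests are
per-parameter, as is conventional for trajectory panels). Reports embed
the package version, seed and a configuration hash, and omit
timestamps, so identical inputs give byte-identical outputs.

## Problem sizes used in validation

The shipped checks run the pipeline at the study's own scale: 72-h
windows at 18-min sampling (240 samples), ladders of 4–8 animals per
age group, 100–200 replicate cohorts for stochastic summaries, and a
40-animal ladder for clock training. These sizes were chosen as the
smallest at which the stochastic summaries stabilize.

## A worked example

```{r example, eval = FALSE}
library(eeclock)

# ground-truth cohort: the five-age ladder, 4 animals per group
coh <- simulate_cohort(default_ladder_spec(4, seed = 1))

# trajectory analysis: daily means, rhythms, ordination, comparisons
tr <- run_trajectory(coh$recordings)
tr$ee_decline_pct                 # ~50 (% EE decline, 6 -> 80 weeks)

# clock on a larger ladder
lf <- simulate_cohort(default_ladder_spec(8, seed = 42))
rhy <- lapply(lf$recordings, cosinor_fit_recording)
ft <- build_feature_table(lf$recordings, rhy)
clk <- train_sparse_clock(ft, seed = 7)
clk$test_metrics                  # held-out RMSE / MAE / R2

# apply to an intervention arm simulated 27 weeks "younger"
tspec <- cohort_spec(data.frame(label = c("Aged", "Treated"),
                                age_weeks = 80, n = 4,
                                intervention_shift_weeks = c(0, 27)),
                     seed = 99)
tcoh <- simulate_cohort(tspec)
tft <- build_feature_table(tcoh$recordings,
                           lapply(tcoh$recordings, cosinor_fit_recording))
run_intervention_eval(clk, tft, aged_group = "Aged")
```

## Known limitations

* The clock interpolates poorly outside or between training ages
  (forest predictions are bounded by the training age range and
  quantized by ladder spacing).
* The periodogram's per-trace period precision is a few minutes at the
  default noise level; single-animal period estimates should not be
  over-interpreted.
* The generator's noise model is stationary AR(1); real cage traces
  show non-stationary episodes (feeding bouts, torpor) that may degrade
  rhythm fits more than the synthetic benchmarks suggest.
* Group comparisons assume independent animals; repeated measures on
  the same animal across sessions are out of scope.
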