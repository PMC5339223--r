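---
title: "Methods: the anger fingerprint pipeline and its synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the anger fingerprint pipeline and its synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angerefp)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the parameters that matter, what the
synthetic cohort does and does not emulate, and the numerical decisions
taken where the design was genuinely open.

## 1. The electrical fingerprint model

The fingerprint predicts an ROI BOLD time course from delay-embedded EEG
band-power features recorded simultaneously:

$$\hat y(t) = \alpha + \sum_{f=1}^{5}\sum_{d=0}^{D-1}
  \beta_{f,d}\, x_e(f,\, t-d),$$

with bands $f$ = delta (1–4 Hz), theta (4–8), alpha (8–12), beta (12–30),
gamma (30–40) — the literature never fixes a canonical set, so the five
classical bands are used — and $D = 6$ delays of 3-s frames, covering the
~18 s over which the hemodynamic response integrates neural activity.
Features are log band power, z-scored per (channel, band) over frames, so
the model is invariant to affine rescaling of the raw features (amplifier
gain, reference choice); a property test asserts this exactly.

**Fitting.** `fit_efp_individual()` solves the ridge problem on
standardized variables, choosing the penalty on the grid
$\lambda \in 10^{-3},\dots,10^{3}$ by *blocked* (contiguous) 5-fold
cross-validation maximizing held-out Pearson r. Contiguous folds are
essential: both signals are strongly autocorrelated, and shuffled folds
would leak the slow trend and overstate fit. At $\lambda = 0$ the solution
is ordinary least squares (asserted against `lm()`).

**The common model.** Individual coefficient grids are clustered
(`cluster_efp_models()`: average-linkage agglomerative clustering under
the distance $1 - r$ between flattened grids, dendrogram cut at 0.5 on
that scale) and the tight cluster with the best cross-validated fit is
kept, excluding outlier models. "One-class ridge regression across all
participants" is not a standard term; this package reads it as a single
shared-coefficient ridge on the stacked, per-subject-standardized rows,
with $\lambda$ chosen by leave-one-subject-out CV
(`fit_efp_common()`). Per-subject standardization makes subjects
commensurable and leaves the common model intercept-free on the
standardized scale.

**Electrode selection.** The amygdala-model electrode is not fixed a
priori, so `select_electrode()` fits the common model per candidate
channel and keeps the best leave-one-subject-out mean r, breaking ties by
lexical channel order (deterministic). A frontal-cortex variant is
obtained by fixing the electrode (e.g. `F4`) and skipping selection.

**Output.** `predict_efp()` evaluates the model at the frame rate and
averages non-overlapping bins of $\lceil 1/(0.03 \times 3)\rceil = 12$
frames down to the conventional 0.03 Hz fingerprint rate; a trailing
partial bin is kept, so a 321-s recording yields 9 samples. For
delay-embedding at prediction time the initial frames with missing lags
are padded with the earliest frame (training drops them instead:
`embed_delays(pad = FALSE)` keeps exactly the frames whose lags all
exist, i.e. $n_\text{frames} - D + 1$ rows).

## 2. Inter-subject correlation and its calibration

`isc_map()` computes, per voxel, each subject's Pearson correlation with
the mean time course of all other subjects, Fisher-Z transforms
($\operatorname{atanh}$, $|r|$ clipped to $1-10^{-7}$), and tests the z
values against zero with a two-sided one-sample t across subjects
(df = n − 1). "p < α, Bonferroni corrected" is read as *adjusted*
p = min(1, p·V) below α; thresholding the raw p at α/V is numerically
identical whenever p·V < 1. Time courses are linearly detrended per
subject by default (mirroring upstream high-pass filtering); a constant
series makes r undefined, so such voxels are flagged `NA` and excluded
from inference, never silently zeroed.

**A calibration caveat that the tests document rather than hide.** The n
leave-one-out correlations of a voxel are not independent: each subject
appears in every other subject's reference mean. Under the null they are
exchangeably correlated with pairwise correlation ≈ 1/(n − 1), which
inflates the variance of their mean by the factor 1 + (n−1)·ρ ≈ 2 while
the sample variance in the t statistic *under*-estimates by (1 − ρ). The
squared t statistic is therefore inflated by roughly
2/(1 − 1/(n−1)) ≈ 2.1, and the nominal-0.05 two-sided test rejects about
17% of pure-noise voxels (20 subjects, 107 frames) — the package's null
simulation reproduces this, and it matches the known anticonservativeness
of parametric leave-one-out ISC group tests. The procedure is implemented
in its classical form because that is the form used in practice; users
who need calibrated voxel-wise inference should rely on the heavy
Bonferroni threshold (as the motivating analysis did) or on resampling
methods outside this package's scope.

## 3. Psychophysiology

`rr_to_hr()` converts R-peak times to beats per minute by the
previous-interval rule — between peaks $k$ and $k{+}1$ the instantaneous
value is $60/(t_k - t_{k-1})$ — then resamples into 1-s bins by the
time-weighted mean. The stretch before the second peak has no previous
interval; it is back-filled with the first defined value by default
(`backfill = FALSE` drops those bins instead). A conservation property
pins the rule down: summed bin values / 60 ≈ the number of completed
intervals.

`coupling_stats()` aligns two modalities by resampling the finer series
to the coarser rate with non-overlapping means (the alignment rule is a
package decision; nothing canonical exists for cross-rate rank
correlation), computes per-subject Spearman ρ, and runs a one-sample t on
the raw ρ values — not Fisher-transformed, matching how such couplings
are conventionally reported. Constant series give ρ = NA and are dropped
with a count.

## 4. Ratings, windows, attention bias

Continuous anger ratings live on a 21-level integer grid (seven labelled
levels × 3 steps) sampled at 10 Hz. The high-anger period is the 100-s
window maximizing the sliding mean of the group trace on a 1-s onset grid
(earliest onset wins ties); the low-anger period is fixed to the first
100 s, the most literal reading of its published construction — a
minimizing scan restricted to a range is available via
`find_windows(low_scan = TRUE)`. Windows are half-open `[onset, offset)`
in seconds from recording onset everywhere in the package, and a sample
belongs to a window when its bin centre falls inside.

`score_bias()` applies the standard dot-probe exclusions in a fixed,
single-pass order: (1) incorrect responses, (2) RT < 150 ms, (3) RT
beyond ±2 SD of the subject's mean *for that condition*
(congruent / incongruent / neutral-neutral), with mean and SD computed on
the survivors of rules 1–2 and applied once, not iterated. The published
description names the rules but not their order or iteration; this
deterministic reading keeps scores reproducible and is pinned by a
brute-force oracle test. Bias = mean RT(incongruent) − mean
RT(congruent); positive is vigilance, and an exact zero is assigned to
avoidance by convention (a tie never observed in practice). Neutral
trials pass through the exclusion bookkeeping but never enter the mean.

`mixed_anova()` implements the classical 2×2 mixed design directly from
its orthogonal subject summaries (mean and difference of the two period
values), testing unweighted (type III) cell means so that unequal group
sizes do not contaminate the period effect, with
ηp² = SS(effect)/(SS(effect)+SS(error)) in each effect's stratum. A
noiseless crossover drives the interaction F to infinity (p = 0); fully
degenerate data take the NA path. Simple effects of group within each
period are one-way F tests on that period's values (df 1, n − 2). A
model-comparison oracle (`aov` with a subject error stratum) pins the
balanced case.

## 5. The outcome model

`hierarchical_regression()` fits OLS on z-scored variables per ordered
block: standardized betas, two-sided coefficient p (df = n − p − 1),
cumulative R², tolerance (1 − R² of each predictor on its co-predictors;
an error names any predictor with tolerance < 1e−8), and
ΔF = ((R²ₛ − R²ₛ₋₁)/q) / ((1 − R²ₛ)/(n − pₛ − 1)). Missing rows are
dropped listwise and counted — the motivating cohort's Ns drift across
analyses, so the count is part of the result.

The two-predictor standardized normal equations ($r_{1y} = \beta_1 +
\beta_2 r_{12}$, $r_{2y} = \beta_2 + \beta_1 r_{12}$) invert a printed
table: `reconstruct_two_predictor()` returns the implied predictor
intercorrelation, second validity, R² and tolerance, and a property test
shows the round trip through a fitted model is exact to machine
precision. Applied to the published coefficients
(`ptss_reference_models()`), the implied step-2 R² values agree with the
printed ones within 0.002, and the implied tolerances within ~0.004 —
the residue of printing betas to three decimals. The structure is a
textbook *suppression* pattern: the fingerprint's marginal validity with
the outcome is ≈ −0.01, yet its standardized beta is ≈ 0.51, because it
removes criterion-irrelevant variance from state-anger (the two
predictors correlate ≈ −0.66).

## 6. What the synthetic cohort emulates — and what it does not

One latent anger-intensity trace stands in for the film: a trapezoid
(baseline 0, amplitude 1, 20-s linear ramps, plateau 205–285 s inside the
published 189–288 s high-anger period, 321-s recording at 10 Hz) plus
AR(1) noise (φ = 0.9 per 10-Hz sample) with stationary SD 10% of the
amplitude. All subjects share the trace (the stimulus), and every
modality derives from it:

* **BOLD** — latent ⊗ canonical double-gamma HRF (gamma shapes 6 and 16,
  scale 1, undershoot ratio 1/6, unit-sum), binned to the 3-s TR;
  coupled voxels add Gaussian noise at `bold_snr` = 1 (variance ratio,
  per voxel); the ROI mean over 10 coupled voxels therefore has an
  effective SNR near 10, which puts individual fingerprint CV fits in
  the 0.4–0.5 range reported for models of this kind.
* **EEG features** — the ground-truth weight grid is separable: channel
  gain (F8 dominant = the planted target, F4/F7/F3/Fz weaker, Pz null) ×
  spectral profile (alpha −1.0, beta −0.4, delta 0.3, theta 0.5, gamma
  0.6; the classical sign pattern of band-power/BOLD coupling) × a delay
  profile decaying as exp(−lag/7.5 s). The decaying profile, rather than
  a peaked one, is what makes the grid a *recoverable* ground truth: with
  a strongly autocorrelated latent the delayed feature copies are nearly
  collinear, so any estimator necessarily spreads weight smoothly across
  lags, and only a smooth truth is identifiable. Noise is pink across
  bands (power ∝ 1/f, SD ∝ 1/√f), calibrated so signal/noise variance at
  the target electrode equals `eeg_snr` = 2.
* **Heart rate** — inter-beat intervals 60/(70 + 8·latent) s with 20-ms
  jitter; **ratings** — latent lagged 2 s, scaled to levels 2–16,
  noise SD 1 level, rounded and clamped to 0–20; **dot-probe** — lognormal
  RT body (median 520 ms, σ = 0.15), congruent trials shifted by the
  subject's true bias, 3% fast guesses and 5% errors so the exclusion
  rules have work to do; true biases are drawn N(2, 18) ms so both
  vigilance and avoidance groups arise.
* **Outcomes** — a trivariate Gaussian over (state-anger, fingerprint
  high-window mean, PTSS) with correlations (−0.661, 0.454, −0.011)
  solved from the published two-predictor algebra (eigenvalues all
  positive; implied population R² = 0.3545), PTSS mapped to the
  17-item-checklist scale (mean 27.6, SD 9.4), rounded then clamped to
  [17, 85]. With these published moments the floor sits only ~1.1 SD
  below the mean, so roughly one draw in eight clamps — an unavoidable
  consequence of a bounded scale with those moments; the unclamped value
  is kept in `ptss_raw` so the Gaussian structure remains checkable, and
  the clamped integer score is what the regression consumes. At n = 33
  the clamping attenuation and the small-sample inflation of R² nearly
  cancel, which is why the 500-cohort recovery mean lands close to the
  population 0.354.

The generator does **not** emulate: MR-gradient, cardioballistic or
ocular artifacts; head motion; fMRI preprocessing; spatial structure
within the ROI (voxels are exchangeable); any systematic link between
attention-bias group and fingerprint coupling (an optional
group-difference effect exists conceptually but ships disabled — the
motivating data give no effect size for it); or a between-subject bridge
from the *measured* fingerprint series to the outcome table (the outcome
table's fingerprint column carries the published correlation structure
directly, while the time-series branch calibrates within-subject signal
recovery — linking the two would require assumptions the source analysis
does not license). Passing tests therefore show the *procedures* are
correct and recover planted structure at realistic SNR; they do not show
the markers work on real recordings.

## 7. Numerical choices and problem sizes

Degenerate inputs are handled explicitly everywhere: constant features
are zeroed by the standardizer (and a rank-0 design refuses to fit),
constant voxels and series give NA (never silent zeros), zero-variance
paired differences warn and return NA, and an exact zero bias goes to
avoidance. Ties break deterministically: earliest onset in window scans,
smallest λ on flat CV curves, lexical channel order in electrode
selection. Correlations are clipped at 1 − 10⁻⁷ before Fisher-Z;
tolerances below 10⁻⁸ are treated as collinearity errors.

The packaged test and calibration runs use deliberately moderate sizes —
cohorts of 5–25 subjects, 2000 null voxels × 20 subjects for the ISC
calibration, 50 seeded electrode-recovery runs, 500 outcome cohorts at
n = 33 (the published regression n) — chosen so the whole suite completes
in about a minute while keeping Monte-Carlo error well inside the
assertion margins.

## 8. Known limitations

* The leave-one-out ISC group t-test is anticonservative by construction
  (Section 2); the package reports it faithfully instead of silently
  recalibrating it.
* The common fingerprint model assumes subjects share one coefficient
  grid up to per-subject scaling; real cohorts mix topographies, which is
  precisely why the clustering step exists, but the generator plants a
  single shared grid and so cannot stress that assumption hard.
* Published tolerances and effect sizes are reproduced only to the
  precision their printed inputs allow; a few printed group statistics in
  the motivating analysis are internally inconsistent (e.g. an avoidance
  group of N = 20 reported with t(14)) and are deliberately not used as
  test expectations.
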