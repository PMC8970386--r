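---
title: "A spectral-covariance qEEG index for DLB versus AD: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spectral-covariance qEEG index for DLB versus AD: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem

Dementia with Lewy bodies (DLB) is the second most common degenerative
dementia after Alzheimer's disease (AD) and is frequently misdiagnosed
as AD, which matters clinically: DLB patients are prone to severe
adverse reactions to antipsychotics and respond differently to
cholinesterase inhibitors. Resting EEG carries a well-replicated
discriminating signature — in DLB the posterior dominant rhythm slows
from the alpha band (8–13 Hz) into a "pre-alpha" band (roughly
5.6–7.9 Hz), its frequency is more variable over time, and diffuse slow
activity is more prominent. `dlbindex` turns a routine 150-second
eyes-closed resting recording from the standard 19-channel 10–20
montage into a single calibrated index: negative values read AD-like,
values ≥ 0 read DLB-like, in units of the AD training cohort's
standard deviation.

## The model

Let $x_c(t)$ be the average-referenced, band-pass-filtered signal of
channel $c \in \{1,\dots,19\}$. The 150-s analysis epoch is cut into
$n_{seg} = 149$ two-second segments stepped by one second. For segment
$i$, the Fourier coefficients $\sigma_{cij}$ are taken at the 90
frequencies $f_j = 0.5, 1.0, \dots, 45$ Hz (the native bin spacing of a
2-s window, so no taper or interpolation is involved; coefficients are
scaled by $1/n$ samples so magnitudes do not depend on the sampling
rate).

For every unordered channel pair $(c,k)$ — 19 auto pairs and 171 cross
pairs, 190 in all — the full-spectral-resolution covariance is

$$\chi_{ckij} = \sigma_{cij}\,\overline{\sigma_{kij}}.$$

Auto pairs are the per-channel power spectra (real by construction;
their imaginary slots are kept as structural zeros so every pair
contributes a uniform 90 × 2 block). The per-recording *base features*
are a robust location estimate over segments of the real and imaginary
parts separately — $190 \times 90 \times 2 = 34{,}200$ values.

Each pair's 180-dimensional block is then reduced by principal
component analysis fitted on the training cohort (covariance PCA on
mean-centred blocks), and the **two** most discriminative components
per pair are retained, giving the $2 \times 190 = 380$ *core features*

$$C_{ck\alpha} = \mathrm{E}_i\Big\{\sum_j \chi_{ckij}\,P_{ck\alpha j}\Big\},$$

i.e. each segment is projected onto the loading and the same robust
expectation $\mathrm{E}_i$ is taken over segments. A genetic algorithm
(GA) selects a feature subset, and a linear soft-margin SVM on the
selected features plus age and age² produces a decision value that is
de-standardized into an explicit linear formula

$$I_{raw} = \sum_{ck\alpha} C_{ck\alpha}\beta_{ck\alpha}
          + \beta_1 A + \beta_2 A^2 + \rho,$$

calibrated so that the decision cut-off sits at 0 and one unit equals
one standard deviation of the AD training cohort's raw indices.
Separate models are trained per gender (with a pooled fallback for
sparse strata), mirroring known gender differences in resting EEG.

## Parameters, defaults, and why

| Parameter | Default | Rationale |
|---|---|---|
| Band-pass | 0.1–70 Hz, order-8 Butterworth | covers the full clinical band; 0.1 Hz removes electrode drift, 70 Hz leaves the 45 Hz feature ceiling a wide margin |
| Filter application | zero-phase (forward–backward) | cross-channel covariances depend on relative phase; a causal pass would add frequency-dependent phase it cannot remove |
| Epoch | 150 s | the method's defining recording length; shorter epochs are refused rather than silently accepted |
| Segments | 2 s, stepped 1 s | 2 s gives exactly 0.5 Hz resolution; 50 % overlap yields 149 segments for robust aggregation |
| Frequencies | 0.5–45 Hz | below mains interference and EMG dominance |
| Aggregation over segments | marginal median | see below |
| PCA components ranked, kept | all non-degenerate, top 2 per pair | see below |
| GA | population 50, ≤ 100 generations, crossover 0.5, mutation 0.01 (floored at 1/#features), elitism 2, tournament k = 3, sparse init (density 0.1), parsimony 0.01·|mask|/380, early stop after 8 stale generations (< 0.002 improvement) | see below |
| GA fitness | stratified 5-fold CV-AUC of the linear SVM | AUC is threshold-free; stratification keeps folds balanced in small cohorts |
| SVM | linear, cost 1 | p ≫ n; anything nonlinear overfits immediately |
| Age terms | $A$, $A^2$ always included | lets the hyperplane absorb smooth age effects on spectral power instead of confusing them with diagnosis |
| Index scale | Youden-J cut-off, AD-SD units | see below |
| Gender strata | separate M/F models, pooled below 4 per class | resting spectra differ by gender; tiny strata would overfit |

## Resolutions of underdetermined design points

**Median as the robust expectation.** Blink, muscle and ECG artefacts
contaminate a minority of the 149 segments but can dominate a mean.
The marginal median of real and imaginary parts is the simplest
estimator with a 50 % breakdown point, needs no artefact detector or
tuning constant, and is testable: under seeded broadband bursts the
median-aggregated features are required (and observed) to shift more
than five times less than mean-aggregated ones. A 20 %-per-tail trimmed
mean and the plain mean remain available as `estimator` options for
exactly this comparison.

**Top-2 components by folded AUC.** "The two most discriminative
components per pair" is resolved as the two with the best
$\max(A, 1-A)$ of the training ROC AUC of their subject scores — folded
because the sign of a principal component is arbitrary. Ties fall back
to explained-variance order so the selection is deterministic.
Ranking by variance alone would keep high-power directions that carry
no diagnostic signal.

**Youden's J for the cut-off.** The published operating point of the
index is "0 on a scale in AD-SD units", which presupposes a cut-off
choice on the training ROC. Youden's J (maximizing sensitivity +
specificity − 1) is the standard prevalence-free choice; candidates are
midpoints between consecutive sorted raw indices, with ties resolved
toward the midpoint of the two class medians.

**GA additions.** Population size, generation cap, crossover and
mutation rates, and elitism are conventional values. Our additions are:
*sparse initialization* (each bit on with probability 0.1), because the
parsimony term makes small masks the interesting region and dense
random masks waste the first generations; a *mutation floor* of one
expected flip per child so small problems still explore; *memoization*
of fitness by mask (the population converges, so repeat evaluations are
common); and *early stopping* when the best fitness has not improved by
0.002 over 8 consecutive generations — elitism guarantees the incumbent
best is returned, so stopping early can only miss later improvements,
never lose the current optimum. On an exhaustive 8-feature benchmark
the GA reproduces the global optimum of all 255 masks.

**De-standardized coefficients.** The SVM is fitted on standardized
features, but the model is stored as coefficients of the raw features
($\beta$, $\beta_1$, $\beta_2$, $\rho$), verified to reproduce the SVM
decision values to machine precision. This makes the index an explicit,
portable linear formula rather than an opaque model object.

## The synthetic cohort generator

No clinical data ships with the package; `cohort_spec()` /
`simulate_cohort()` generate seeded surrogate cohorts that encode the
group structure the classifier targets:

- per-channel pink (1/f) background noise (10 µV) plus a shared
  volume-conduction component (3 µV);
- a shared narrow-band oscillation (20 µV, posterior-maximal topography)
  whose instantaneous frequency performs a reflected random walk (SD
  `freq_variability` per second) around the subject's dominant
  frequency;
- a diffuse 1–4 Hz component scaled by the subject's slow-power gain;
- optional blink (frontal, ~0.2 s, 150 µV) and EMG (temporal, > 20 Hz,
  50 µV) artefacts at a configurable events-per-minute rate.

A single `separation` dial $\lambda \in [0,1]$ interpolates the group
parameter distributions: at $\lambda = 1$ the DLB-like group's dominant
rhythm sits in the pre-alpha band (mean 6.8 Hz, clipped to 5.6–7.9 Hz)
with larger frequency variability and more slow power, while the
AD-like group stays alpha (mean 9 Hz); at $\lambda = 0$ the two groups
are identically distributed — a null cohort on which any honest
pipeline must score at chance.

**Scope and limits.** The generator is a validation instrument, not a
brain model: it reproduces the spectral statistics the features respond
to (peak position, peak wander, slow power, cross-channel correlation
through shared sources) but not waveform morphology, non-stationary
vigilance effects, or realistic artefact variety. Conclusions about
clinical performance cannot be drawn from it; conclusions about the
pipeline's correctness, leakage-freedom, and robustness can.

## Validation design and statistical sizing

Two properties are checked end-to-end over seeds 1–10, each run
training on a freshly simulated cohort and evaluating on an
*independent* held-out cohort:

- **Separated cohorts** (λ = 1, 40 + 40 train, 20 + 20 test): held-out
  AUC ≥ 0.9 and accuracy ≥ 0.8 in at least 9 of 10 seeds.
- **Null cohorts** (λ = 0, 40 + 40 train, 40 + 40 test): held-out AUC
  within [0.35, 0.65] in at least 9 of 10 seeds.

The null band and test size were fixed before running: with 40
subjects per class the null AUC is approximately normal with standard
deviation $\sqrt{(n_+ + n_- + 1)/(12\,n_+ n_-)} \approx 0.065$, so a
correct (chance-level) pipeline falls inside [0.35, 0.65] with
probability ≈ 0.985 per run and passes ≥ 9/10 with probability > 0.99.
With only 20 per class the per-run probability drops to ≈ 0.87 and the
10-seed criterion would fail a correct implementation roughly one time
in three — the larger test cohort is a power requirement, not a
convenience. The null check matters because it detects leakage (e.g.
fitting the PCA, ranking, or calibration on test data), which inflates
null AUC away from chance.

## Numerical choices

- **Zero-phase filtering** pads by odd reflection (3× filter order) and
  initializes both passes at the filter's step steady state, so the
  0.1 Hz pole does not leak start-up transients into the epoch. The
  designed magnitude response (squared for the double pass) is exposed
  as `bandpass_response()` for verification against the implementation.
- **Hot paths** (covariance products, robust aggregation, per-segment
  projection, IIR filtering) are implemented in C++
  (RcppArmadillo). Straightforward tensor reference implementations are
  kept exported, and the test suite requires the fast paths to be
  bit-identical to them.
- **PCA** uses the SVD of the centred block; components with singular
  values below $10^{-12}$ of the leading one are dropped as degenerate.
- **Exact statistics**: Clopper–Pearson intervals via Beta quantiles,
  Fisher's exact test via the conditional hypergeometric enumeration,
  both cross-checked against brute-force oracles in the tests.

## Problem sizes used in development

Training cohorts of 40 + 40 (gender strata of roughly 20 + 20) run the
full chain — extraction, per-pair PCA, ranking, GA, SVM, calibration —
in about a minute on one core; single-recording extraction takes
roughly a third of a second. The GA typically converges (stops
improving by > 0.002) within 5–20 generations at these sizes.
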