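---
title: "Methods: chemometric calibration of MIR milk spectra for whey proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometric calibration of MIR milk spectra for whey proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirwhey)
```

`mirwhey` quantifies β-lactoglobulin (β-LG) and α-lactalbumin (α-LA), the
two most abundant bovine whey proteins, from mid-infrared absorbance
spectra of milk. This vignette explains the models and procedures, the
parameters that matter, the synthetic-data generator the package is
validated on, and the numerical and design choices that were genuinely
open.

## The data model

A `spectra_set` is an `n × p` absorbance matrix on a strictly descending
wavenumber axis (canonically 4000 → 400 cm⁻¹), with each row identified by
a spectrum id, a sample id and a replicate index. Replicate spectra of one
physical sample share reference concentrations (a `concentration_table`,
mg/mL per protein) but differ in instrument noise, multiplicative scatter
and baseline state. Keeping the replicate structure explicit is what makes
leakage-aware cross-validation possible downstream.

## Outlier screening: Hotelling T² and Q-residuals

Screening fits a NIPALS PLS decomposition `X = TP′ + E` of the
column-centered spectra, directed at one protein's concentrations, and
computes per-spectrum

* `T²ᵢ = Σⱼ t²ᵢⱼ / s²ⱼ` — the squared, SD-standardized score distance:
  large for spectra extreme *inside* the model space;
* `Qᵢ = e′ᵢ eᵢ` — the squared residual norm: large for spectra the model
  space does not describe.

A spectrum is an outlier when it exceeds both limits ("and" rule, the
default) or either ("or" rule) at a confidence level, default 0.99.
Choices worth knowing:

* **Component count.** The number of screening components is not a
  meaningful user quantity, so the default is the smallest `k` explaining
  ≥ 95% of the centered X sum of squares, capped at 10 — conventional
  chemometric practice, exposed as an argument.
* **T² limit.** The F-distribution form `k(n−1)/(n−k) · F(k, n−k, α)`.
* **Q limit.** Jackson–Mudholkar's parametric limit computed from the
  eigenvalues of the residual covariance. The eigenvalues are estimated
  from the rows in the central 90% of the Q distribution (10% trim). The
  trim matters: with, say, 7% gross contamination, the outliers' own
  residuals would otherwise dominate the eigenvalue sum and inflate the
  very gate that is supposed to catch them, letting moderate outliers
  (large Q relative to clean spectra, small relative to the gross ones)
  escape. Trimming the scale estimate — while still fitting the
  decomposition once, on all spectra — keeps the gate calibrated to the
  clean majority. A plain empirical quantile of Q is available
  (`q_method = "empirical"`) but is not the default precisely because a
  contaminated empirical distribution pushes its own 99% quantile into the
  outlier group.
* **Screening happens once, before partitioning**, on all spectra
  jointly; there is no iterative re-screening.

## Partitioning

* `kennard_stone()` is the classical max–min-distance selection: the first
  two picks realize the maximum pairwise Euclidean distance; each later
  pick maximizes its minimum distance to the selected set. Ties break to
  the lowest row index, making the algorithm fully deterministic and
  testable against a brute-force oracle.
* `ks_split()` selects the *calibration* set by Kennard–Stone (on the
  spectra or on one protein's concentrations) and leaves the remainder for
  validation. The validation size is `floor(fraction · n)` — the rounding
  convention that maps 197 spectra at 30% to exactly 138/59.
* `random_split()` is the seeded spectrum-level alternative. Spectrum-level
  splitting can place replicates of one sample on both sides; that is kept
  as the default for comparability, but the replicate-aware CV schemes
  below are the recommended guard.
* `cv_folds()` builds LORO folds (fold r validates replicate r of every
  sample that has one; samples lacking replicate r simply contribute
  nothing) and LOSO folds (one fold per sample, all its replicates held
  out). LOSO is the stricter scheme: no replicate of a validated sample
  ever appears in training, so it bounds performance from below, while
  LORO bounds it from above.

## Preprocessing and the ordered search

Stage order is fixed — (1) scaling, (2) scatter/baseline correction,
(3) Savitzky–Golay smoothing — and any stage can be skipped:

| Stage | Options | Notes |
|---|---|---|
| scale | `normalize`, `mean_center` | "normalize" is row-wise unit Euclidean norm (the definition is not universal; min–max is deliberately not used). Mean-centering is learned on calibration columns only. |
| scatter | SNV, RNV, LSNV, MSC, EMSC, polynomial detrend ("baseline") | SNV uses the sample (n−1) SD; RNV divides by an interquantile range (default 25/75 percentiles); LSNV applies SNV inside contiguous windows (default 151 points); MSC regresses each row on the calibration-mean reference and corrects `(x − b)/a`; EMSC adds a polynomial (default order 2) in the wavenumber to the regression; "baseline" subtracts a least-squares polynomial (order 2) per row. |
| smoothing | Savitzky–Golay | odd window, polynomial order, derivative order 0–2; derivative is per index step. |

MSC/EMSC after mean-centering is mathematically degenerate (the reference
spectrum is ~0, so the gain regression is undefined); the operators detect
this and raise an error, and the pipeline search records such chains as
failed and moves on rather than silently producing noise.

`search_best_pipeline()` evaluates every chain by: fit states on the
calibration matrix, transform the validation matrix with those states
only, fit PLS per component count (1–20 by default) for each protein, and
score validation R². The two proteins are aggregated with `min` (the
conservative choice; `mean` is available) and ties break to the smaller
component count, then grid order. The default grid — 2 scaling options ×
(6 corrections + skip) × (10 windows × 3 polynomial orders + skip) — has
434 chains; the grid is fully configurable and nothing downstream depends
on its exact composition.

The no-leakage contract is testable: transforming a permuted or subset
validation matrix must reproduce the corresponding rows exactly, because
no validation statistic is ever read.

## Two-stage wavenumber selection

1. **iPLS.** The axis is split into equidistant intervals (20/25/30 are
   the conventional choices); each interval's PLS model is scored by
   cross-validated RMSE (fixed fold seed) and intervals are ranked. The
   top intervals localize the informative regions — in milk, the amide II
   band (≈1480–1575 cm⁻¹) is typically prominent because the strong water
   band overlaps amide I.
2. **Binning + GA.** The (optionally region-restricted, canonically
   3000–1000 cm⁻¹) axis is binned by summing `bin_width = 17` contiguous
   points (`n_bins = floor(p/17)`, remainder dropped with a warning), and
   a genetic algorithm evolves binary bin masks: tournament selection
   (size 3), single-point crossover (rate 0.8), bit-flip mutation (rate
   0.01), elitism (2). Fitness is the negative cross-validated PLS RMSE of
   the selected bins, components capped at `min(10, #bins)`, folds fixed
   per study so chromosomes are comparable. Chromosomes from the top iPLS
   intervals seed part of the initial population. The GA is repeated
   (default 5 runs); each run's best mask is tallied and the final mask
   keeps bins selected in at least half the runs. The selection frequency,
   not a single run, is the stable quantity.

Defaults worth stating: population 200 and 100 generations mirror the
conventional scale for this problem class; the per-bin frequency
threshold (0.5) is a design choice — the "right" threshold depends on how
aggressively one wants to prune, and it is exposed in `ga_config()`.
Because GA operator rates are conventions rather than derivable
quantities, all of them are configurable.

## Calibration models

All families fit one protein at a time:

* **PLS** — the package's own NIPALS implementation, shared with the
  screening stage. Loadings are normalized to unit norm (scores absorb the
  scale), which makes per-component score SDs comparable; regression
  coefficients are kept for every truncation so component scans are cheap.
  Coefficients and predictions are invariant to the per-component sign
  indeterminacy.
* **SVR** — ε-insensitive support vector regression (libsvm via `e1071`),
  kernels linear/RBF/polynomial. Inputs are standardized column-wise with
  calibration statistics before the solver; without this the conventional
  C/γ search ranges are meaningless across preprocessing choices.
* **Ridge** — exact solution of `min ‖Xw − y‖² + α‖w‖²`, by the primal
  normal equations when `p ≤ n` and the exact dual form
  `w = X′(XX′ + αI)⁻¹y` when `p > n`. A `solver` label is accepted for
  provenance but the closed form is always used.
* **LR** — minimum-norm least squares (`α = 0`). With `p ≫ n` this
  interpolates the training data and can extrapolate catastrophically on
  held-out spectra; the package reports the resulting (possibly hugely
  negative) R² as computed. Surfacing this failure mode is intentional —
  it is the reason regularization exists.

`tune_model()` is a budgeted random search over per-family spaces
(log-uniform for C/γ/α, uniform for ε, categorical for kernel and degree,
integer for PLS components), scored by mean 5-fold CV RMSE with seeded
folds. Random search was chosen as the tuner because it is simple,
reproducible, and parallelizable; the spaces follow the conventional
ranges and are shipped in `default_search_spaces()`.
`reference_hyperparameters()` records hyperparameter values reported as
optimal on the original instrument dataset this workflow derives from —
they are data-dependent reference points, not defaults, and are not
expected to be optimal on synthetic data.

Metrics are `R² = 1 − SS_res/SS_tot` and `RMSE = √(mean (y − ŷ)²)` in
mg/mL; on an external validation set these are R²P and RMSEP.

## The synthetic generator: what it emulates, and what it does not

`generate_dataset()` draws clean spectra from a Beer–Lambert mixture
`A(ν) = Σₖ cₖ εₖ(ν)` with Gaussian band shapes:

* β-LG bands at 1632 (amide I, β-sheet region) and 1530 cm⁻¹ (amide II);
  α-LA bands at 1658 (amide I, α-helix region) and 1548 cm⁻¹ (amide II);
* nuisance components: milk-fat C–H stretches (2920, 2852 cm⁻¹) and ester
  carbonyl (1745 cm⁻¹) with per-sample fat level, a lactose band
  (1045 cm⁻¹), and a broad fixed water band overlapping amide I —
  the overlap that makes amide II the more reliable protein region in
  real milk spectra;
* per-sample concentrations from a Gaussian copula with uniform marginals
  over 2.22–4.60 mg/mL (β-LG) and 1.08–2.08 mg/mL (α-LA) and a latent
  shared "total whey" factor targeting Pearson ρ = 0.6 (the latent
  correlation is adjusted, `2·sin(πρ/6)`, so the realized correlation of
  the uniform marginals matches the target);
* per-replicate distortions: LogNormal multiplicative gain
  (`scatter_sd = 0.04` log-SD — the standard generative model that MSC/SNV
  invert), additive offset plus linear drift (`baseline_sd = 0.01` AU),
  and white noise (`noise_sd = 0.002` AU);
* 42 samples × ~5 replicates totalling exactly 212 spectra by default,
  with counts jittered between 4 and 6 so LORO fold logic is exercised;
* `inject_outliers()` adds a gross baseline shift plus a Gaussian-bump
  shape distortion scaled to a multiple (default 10) of the row SD.

Band shapes are Gaussian rather than Lorentzian/Voigt, there is no
instrument line-shape or ATR-penetration model, and the noise scales were
fixed once at values that give realistic-looking signal-to-noise rather
than fitted to any instrument. Consequently, passing tests demonstrate
that the algorithms are implemented correctly and behave as designed
under a controlled generative model — not that any particular accuracy
will be achieved on real milk spectra, where band overlap, nonlinearity
and instrument drift are harsher.

## Numerical choices and degenerate inputs

* NIPALS stops a component early only when the weight vector underflows
  (deflated covariance ≈ 0); the decomposition then truncates with a
  warning rather than fabricating components.
* PLS rank bound `k ≤ min(n − 1, p)` is enforced as an error.
* SNV/RNV/normalize raise named errors on constant or zero-norm rows;
  the search treats those as per-chain failures.
* Kennard–Stone ties (equal distances) break to the lowest index;
  exhaustive-oracle tests rely on this determinism.
* GA chromosomes that mutate to all-zero masks are repaired by activating
  one random bin; fitness caching is keyed on the mask so repeated
  evaluation is free.
* Confidence 1.0 yields infinite (T², Jackson–Mudholkar) or maximal
  (empirical) limits; nothing is flagged.
* All stochastic stages take explicit seeds; the orchestrator derives
  per-stage seeds deterministically from one master seed, so a study is
  reproducible bit for bit.

## Problem sizes in the tests and acceptance script

The validation suite runs the full workflow at reduced scale so the whole
suite completes in minutes on one core: spectra of 120–600 points
(occasionally 10,268 points for pure binning arithmetic), 18–42 samples,
GA populations of 16–40 over 8–30 generations with 1–5 runs, and
preprocessing grids of 4–16 chains (the full 434-chain default grid is
enumerated and counted, and its operators are each tested individually).
These sizes are the package's own testing choices; all of them scale up
by configuration.

## Known limitations

* The preprocessing search optimizes validation R² once on the chosen
  split; it is not nested inside cross-validation, so the winning chain's
  reported R² is mildly optimistic.
* A single GA mask selected on the calibration set is reused across CV
  folds in the study report (an optimistic-bias caveat, documented rather
  than hidden; per-fold re-selection would multiply runtime).
* Wavelet, OSC and reference-based detrending are out of scope, as are
  robust-PCA screening alternatives, and multi-output models.
* The minimum-norm LR family is intentionally fragile (see above).
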