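---
title: "Optimizing spectral preprocessing pipelines: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing spectral preprocessing pipelines: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specopt)
```

## The model

`specopt` selects a spectral preprocessing pipeline for a regression
task by treating the choice as a black-box maximization problem. The
decision variable is a two-coordinate vector
$\theta = (u, e)$: $u \in [0, |\mathcal{C}|)$ indexes (after flooring)
an enumerated list $\mathcal{C}$ of valid pipeline configurations, and
$e \in [-6, 6]$ is the base-10 exponent of the ridge regularization
strength $\alpha = 10^{e}$ of the estimator appended to every
pipeline. The objective is the negative cross-validated RMSE of
"decoded pipeline + ridge" on the training set; an external test set
may substitute for CV, but that branch is off by default because
selecting pipelines on test data biases the final assessment.

Three modelling assumptions matter:

* **Replicates are exchangeable noise around one sample.** All rows
  sharing a group id are kept on one side of every split. Violating
  this (row-level CV on replicated data) typically halves the apparent
  RMSE while saying nothing about new samples.
* **Preprocessing state is part of the model.** Scatter references,
  column statistics and projection bases are *fitted parameters*;
  every CV fold refits them on its training side only. A transform
  never re-estimates state from the data it is applied to.
* **Failures are information.** A configuration that produces a
  singular solve or non-finite output (SNV on a constant spectrum, MSC
  against a flat reference) is not patched with epsilon floors; it
  receives the fixed penalty score $-10^{6}$, which dominates every
  achievable $-\mathrm{RMSE}$ on bounded data, and the optimizer
  learns to avoid it.

## The search space

Pipelines are *ordered* sequences (a Savitzky–Golay derivative before
a scaler is not the scaler before the derivative), without repeated
steps, of user-allowed lengths (default 1–2). Incompatibility rules
remove conceptually redundant combinations: at most one
scatter-correction method (SNV, MSC, EMSC, LSNV, RNV), at most one
scaling/normalization method, at most one dimensionality reduction,
plus two explicit pair bans (SNV with the row standardizer, autoscale
with the standard scaler) kept verbatim even though the family rules
imply them. Each step's tunable parameters are folded in as discrete
grids (e.g. Savitzky–Golay window ∈ {5, 7, 11, 15}, polynomial order
∈ {2, 3, 4}, derivative ∈ {0, 1, 2}; MSC reference ∈ {mean, median}),
so the single index coordinate is the only discrete dimension the
optimizer sees. Whether to enumerate ordered or unordered sequences
was genuinely open; ordered was chosen because reported optimal
pipelines in this field distinguish direction (derivative → scaler for
fat, scaler → detrend for lactose).

The registry accepts any Savitzky–Golay polynomial order below the
window length, beyond the default search grid, because published
pipeline tables occasionally use values (e.g. order 5 at window 13)
outside the grid actually searched.

## Operator definitions

The field names these operators without printing formulas, so the
package fixes the conventional definitions and treats them as design
decisions:

* **SNV** $(x - \bar{x}) / s_x$ per row, with the *sample* (n−1)
  standard deviation — making `[1, 2, 3] → [−1, 0, 1]` exact. The
  scaler family instead uses the population (ddof 0) convention of the
  general ML toolkits it mirrors, making "column values {0, 2} → mean
  1, scale 1" exact. The two conventions coexist deliberately.
* **MSC**: per-row OLS $x = a + b\,r$ against the train-mean (or
  -median) reference $r$; corrected $= (x - a)/b$. **EMSC** adds
  $\tilde\lambda, \tilde\lambda^2$ regressors, with the wavenumber
  axis rescaled to $[-1, 1]$ to stabilize the normal equations; order
  0 reduces exactly to MSC.
* **RNV**: $(x - P_q(x)) / \mathrm{sd}(x[x \le P_q(x)])$ with $q=25$
  and linear-interpolation percentiles. **LSNV**: SNV in
  non-overlapping windows (default 100 points), the trailing partial
  window standardized on its own; a window spanning the spectrum
  reduces to SNV.
* **Savitzky–Golay** derivatives are taken with respect to the point
  index, not divided by the ~4 cm⁻¹ grid step; downstream scalers and
  the ridge absorb the constant factor.
* **Detrending**: subtract a least-squares line ("simple"),
  polynomial of given order, or least-squares cubic B-spline with
  knots every `dspline` points.
* **Asymmetric least squares baseline**: iterate
  $z = \arg\min_z \sum_i w_i (x_i - z_i)^2 + \lambda \sum (\Delta^2
  z)^2$, $w_i = p$ above the baseline and $1-p$ below, with
  $\lambda = 10^5$, $p = 0.01$, 10 iterations. The solve is performed
  on the mean-centered row: the second-difference penalty annihilates
  constants exactly, so the flat component carries no error from the
  ill-conditioned ($\kappa \sim 10^6$) system.
* **Dimensionality reductions** (PCA, kernel PCA, FastICA, LLE)
  default to 10 components, matching the latent-variable cap used for
  PLS. FastICA (logcosh contrast, symmetric decorrelation) and LLE
  (k-NN reconstruction weights, bottom eigenvectors) are implemented
  in-package with explicit seeding.

## The optimizer

The surrogate is a Gaussian process with Matérn-5/2 kernel,
per-dimension length-scales, and amplitude and noise estimated by
marginal-likelihood maximization (L-BFGS-B, two restarts, noise floor
$10^{-6}$). Acquisition is Expected Improvement with exploration
offset $\xi = 0.01$, maximized over 1000 uniform candidates — plus,
when the first coordinate spans an integer range, one candidate at
every cell midpoint so no pipeline index is unreachable in a given
round — followed by local refinement from the best five. The discrete
index is handled by continuous relaxation and flooring at decode time;
no special kernel is used. Defaults are `ninit = 50` random
evaluations then `niter = 200` guided ones; the validation studies in
the test suite use reduced budgets (10 + 40) on spaces of ≤ 60
configurations.

Determinism: with a fixed seed the full trace is reproducible
bit-for-bit on one platform. Evaluations that fail enter the GP at a
pessimistic floor (two standard deviations below the worst success)
rather than at $-10^6$, which would flatten the surrogate.

## Cross-validation and stage 2

The default objective uses 5 group-shuffle splits holding out 25% of
groups each (the split count follows the fold-level statistical
protocol below; the fraction is a package choice). Exhaustive
leave-P-groups-out is available, capped at 10 000 folds. In stage 2
the winning pipeline is frozen and six regressors are tuned on the
training groups only — PLS (latent variables 2…min(10, features)),
SVR (RBF; C ∈ [0.1, 100], ε ∈ [0.01, 1], γ ∈ [10⁻⁴, 1] log-scale),
Elastic Net (l1 ratio ∈ [0.1, 0.9], penalty ∈ [10⁻⁴, 1]), GBM
(50–300 rounds, learning rate 0.01–0.3, depth 3–10, minimum split
2–10) by the same Bayesian optimizer (budgets 5 + 100; PLS 5 + 10),
while RidgeCV (internal log-spaced 10⁻⁶…10⁶ grid) and the 5-fold-CV
lasso tune themselves. Test metrics are computed exactly once per
(component, model), and any group appearing on both sides is a hard
error. The lasso backend solves the coordinate-descent path rather
than least-angle regression; at the selected penalty the solutions
coincide.

## Statistical comparison

Fold-level RMSEs of an optimized pipeline and a baseline condition are
compared pairwise: Shapiro–Wilk on the differences gates between the
paired *t*-test (p > 0.05) and the Wilcoxon signed-rank test, the
latter using the exact null for n ≤ 25 without ties and the
continuity-corrected normal approximation otherwise — at 5 folds the
exact null is essential. Effect size is paired Cohen's
*d* = mean(diff)/sd(diff) (sample sd), negative when the optimized
pipeline has lower RMSE; the 95% CI is the *t*-interval
mean ± t₀.₉₇₅,ₙ₋₁·sd/√n. Families of comparisons are
Bonferroni-corrected with K equal to the number of comparisons
actually run (the canonical design is 2 models × 4 components × 3
baselines = 24); identical conditions short-circuit to p = 1 rather
than an undefined test statistic.

## The synthetic generator

The generator emulates milk MIR acquisition: 1060-point grids from
4999.99 to 925.07 cm⁻¹ (~4 cm⁻¹ steps); fat/protein/lactose drawn
from a trivariate normal with means (5.5679, 4.7644, 4.5607) % w/w,
sds (0.8178, 0.5065, 0.1152) and correlations r(fat, protein) = 0.38,
r(protein, lactose) = −0.58, r(fat, lactose) = 0 (the last is an
assumption — no value is documented for it); total solids = the three
components + 1.2560 residual solids + N(0, 0.36²), which reproduces
both the observed total-solids spread (~1.14) and the strong
fat/total-solids correlation (~0.88). Values are clipped to the
documented component ranges; because the fat and total-solids upper
bounds sit only ~1.2–1.5 sd above their means, clipping biases those
two means low by up to ~0.05 — a known, accepted artifact of using a
truncated normal for data that are in reality negatively skewed.
Component spectra are sums of Gaussian bands at the canonical
assignments (fat: 2922, 2852, 1743 cm⁻¹; protein: 1635, 1548 cm⁻¹;
lactose: 1077 cm⁻¹), peak-normalized; Gaussian shapes (not
Lorentzian/Voigt) suffice for exercising transforms. Clean spectra
are Beer–Lambert mixtures over a broad fixed continuum; each
replicate then receives multiplicative scatter (gain ~ N(1, σ_b),
offset ~ N(0, σ_a)), an additive random polynomial baseline, and
i.i.d. noise. Presets: `none`, `scatter` (σ_b = 0.2, σ_a = 0.1 — the
planted benchmark), `baseline`, `full`.

What passing on synthetic data shows — and does not: the generator has
exactly linear mixing, Gaussian bands, and corruption matched to the
operators that remove it. Real spectra add instrument line-shape
effects, water-absorption structure, nonlinear detector response and
temperature drifts; success here validates the *machinery* (no
leakage, correct operator algebra, a working optimizer), not any claim
about a particular instrument's data.

## The planted-scatter benchmark

Optimizer recovery is validated against exhaustive search on a small
strongly scatter-corrupted dataset (40 groups × 2 replicates,
200-point grid, zero baseline). The benchmark space is
{MSC, detrend, scaler} × lengths [1, 2] — nine configurations with
exactly *one* scatter-correcting candidate. That restriction is
deliberate: spaces containing several scatter corrections, or steps
that are no-ops under a centering ridge (mean-centering, derivative-0
smoothing at low noise), contain exact or near ties (ΔRMSE ~ 0.3%)
that make "find the unique argmax" meaningless for any optimizer at a
50-evaluation budget. The exhaustive oracle scores every
configuration over a quarter-decade grid of the ridge exponent, since
the CV score can be sharply alpha-sensitive near its optimum. Under
this design the optimizer recovers the exact winner in ≥ 9 of 10
seeds and a scatter-correcting pipeline in all of them.

## Numerical choices and degenerate inputs

* Rounding of group counts is half-away-from-zero, so a 70/30 split
  of 193 groups gives 135/58 regardless of banker's-rounding
  behavior. Distance ties in Kennard-Stone (the seeding pair and each
  max–min addition) break toward the smallest group index in
  first-appearance order.
* The stage-1 ridge is solved by centered normal equations with a
  Cholesky factorization, falling back to a QR least-squares solve,
  and failing to the penalty — mirroring linear-algebra-error
  semantics rather than silently regularizing.
* Constant columns pass through scalers unscaled (scale 1), matching
  the general-ML convention; constant *rows* under row-wise
  standardization are ill-conditioning, by design.
* Spectra tables are written with `%.17g`, so read → write → read
  round-trips are bit-identical.

## Problem sizes used in validation

The test suite exercises the full protocol at reduced scale: 193
groups × 50 points for the split-count reproduction, 40 × 200 for the
optimizer-recovery benchmark (10 seeds, 10 + 40 budget), 100
randomized datasets for the leakage audit, and 5000 simulated null
families for the type-I calibration of the paired-*t* branch (observed
rejection rate within [0.03, 0.07] at α = 0.05). These sizes are the
package's validation design and run in minutes on one CPU.

## Known limitations

* Pipelines longer than three steps explode the enumeration; the
  space is designed for the short pipelines that work in practice.
* The GP treats the pipeline index as a continuous axis; nothing
  enforces smoothness of neighboring indices, and with enumerations
  beyond a few hundred configurations random exploration dominates.
* The generator does not model water absorption physics or instrument
  line shapes, and truncation biases the clipped component means (see
  above).
* Wavenumber-region selection is out of scope; pipelines operate on
  the full spectrum.
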