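---
title: "Methods: QCR viscometry and classification of synovial fluid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QCR viscometry and classification of synovial fluid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcrsf)
```

This vignette is the package's own account of the models it implements,
the choices made where the design was genuinely open, and what its tests
do and do not establish.

## 1. Sensing model

A quartz crystal resonator driven near resonance behaves, over a narrow
band, like a series resonant branch whose conductance is Lorentzian:

$$G(f) = \frac{G_{max}}{1 + \left((f - f_s)/\Gamma\right)^2},$$

with series resonance frequency $f_s$ and half-bandwidth at half-maximum
$\Gamma$. `simulate_sweep()` generates exactly this curve (optionally with
multiplicative Gaussian noise); no equivalent-circuit fitting
(Butterworth–Van Dyke) is attempted — the Lorentzian is the minimal,
analytically checkable near-resonance form, and susceptance, overtones and
temperature effects are out of scope.

Loading the crystal with a semi-infinite Newtonian liquid of density
$\rho_L$ and viscosity $\eta_L$ shifts the resonance down by the
Kanazawa–Gordon relation

$$\Delta f = -\, n\, f_0^{3/2} \sqrt{\frac{\rho_L \eta_L}{\pi \rho_q G_q}},$$

implemented in `kanazawa_frequency_shift()` with the quartz constants
$\rho_q = 2648$ kg m$^{-3}$, $G_q = 2.947\times 10^{10}$ N m$^{-2}$,
$f_0 = 10$ MHz, $n = 1$. `invert_viscosity()` solves this for $\eta_L$
given an assumed density. The dissipation response is modelled as
proportional, $\Delta\Gamma = r\,|\Delta f|$, where the dimensionless
viscoelastic ratio $r$ equals 1 for an ideal Newtonian liquid; synovial
fluid measured with this sensor type shows $r \approx 0.49$, and the
package treats $r$ as an empirical property of the fluid/tube combination.

**Assumed density.** Converting $\Delta f$ to viscosity requires a fluid
density the instrument does not measure. The package fixes
`synovial_density = 951.93` kg m$^{-3}$ — the unique density that
reconciles the EDTA-tube inflammatory class means
($\Delta f = -3665.36$ Hz, $\eta = 3.46$ mPa s) under the relation above.
No single density reconciles all four class/tube mean pairs (the implied
values span roughly 929–971 kg m$^{-3}$), so this constant is a
calibration choice, exposed as a parameter everywhere it enters, and the
viscosity feature should be read as "Kanazawa-equivalent viscosity at the
reference density".

## 2. Sweep processing

`locate_resonance()` estimates $(f_s, \Gamma, G_{max})$ from a sampled
conductance curve:

* **Peak abscissa** by a least-squares parabola over the contiguous grid
  points above 90% of the raw maximum (minimum: the three points around
  the argmax, where the fit reduces to the interpolating parabola). A
  bare argmax would quantize $\Delta f$ to the sweep step; a three-point
  vertex is exact for noiseless data but noise-dominated on fine grids —
  with a 500-point sweep and 1% conductance noise its median error
  exceeds the grid step, while the windowed fit keeps the median error
  below one step (the property the test suite asserts over 200 seeded
  noisy sweeps).
* **Half-bandwidth** as half the distance between the two half-maximum
  crossings, each linearly interpolated between bracketing grid points.
  The half level references the *fitted* peak, not the raw maximum,
  reducing noise bias.
* **Failure modes** are explicit errors: a maximum on the grid boundary
  ("peak-truncated"), a missing crossing on either side
  ("bandwidth-truncated", which also covers constant curves), and
  non-finite conductance. No smoothing is applied before extraction.

`featurize_pair()` composes extraction on the (air, loaded) pair,
differences the estimates, and inverts the frequency shift to a
viscosity. Defaults for the unloaded reference, where the instrument's
values are not published: resonance at $f_0$ and an air half-bandwidth of
150 Hz (a plausible high-Q value); sweep grids span $\pm 6\Gamma$ with
500 points.

## 3. The synthetic cohort generator

No clinical data are deposited, so the cohort module generates synthetic
measurement tables with the structure the analysis depends on:

* **Geometry.** EDTA: 25 inflammatory + 8 infectious samples, 4972 rows;
  lithium heparin: 21 + 7, 5248 rows; 3–5 repeats per sample × 50 points
  per repeat. Because the published row totals are not divisible by 50,
  repeats are drawn uniformly from 3–5 and then whole repeats are removed
  from the last samples backwards (never below the range minimum) until
  the residual is smaller than one repeat, which is absorbed by a partial
  final repeat — every sample keeps at least one full repeat and the
  total is exact. Any decomposition consistent with the published
  geometry is admissible; this one is the simplest reproducible rule.
* **Class marginals.** Per-class means and SDs of $\Delta f$,
  $\Delta\Gamma$ and $\eta$ default to the published class statistics per
  tube (`class_feature_stats()`).
* **Hierarchy.** Each sample draws a mean frequency shift
  $m \sim N(\mu_c, f\,\sigma_c^2)$ and points scatter as
  $N(m, (1-f)\,\sigma_c^2)$, where $f$ is `between_sample_fraction`.
* **Physical coupling.** Within a point, $\Delta\Gamma$ and $\eta$ follow
  $\Delta f$ through *class-independent* links — the tube-level
  viscoelastic ratio and the Kanazawa inversion — centered at the
  sample's own mean, plus an independent per-sample effect and point
  noise. Variance budgets hold each feature's class-marginal mean and SD
  exactly at the configured values while keeping the within-sample share
  at $(1-f)$; `link_noise_rel` (default 1% of the class mean) caps the
  point-noise component inside that budget. Making the links
  class-independent matters: links calibrated per class would encode the
  diagnosis into the feature coupling itself and let any classifier
  separate the classes without reference to sample structure, destroying
  the leakage phenomenon the cohort must exhibit.
* **Calibration of the clustering.** `between_sample_fraction` is the one
  deliberately tuned constant: it controls how identifiable individual
  samples are from single points, hence where point-split classification
  accuracy lands. It was calibrated once per tube against the observed
  accuracy bands — 0.85 for EDTA (accuracies ~0.85–0.92) and 0.99 for
  lithium heparin (~0.97–0.99) — and then frozen. Physically this says
  EDTA measurements were less repeatable within a sample than heparin
  measurements relative to their biological spread; the published
  per-tube accuracy gap cannot be produced by the class marginals alone,
  which differ little between tubes.
* **Covariates.** White blood cell count is drawn log-normally
  (moment-matched to the class mean ± SD, reflecting its strong right
  skew); neutrophil percentage, glucose and protein are truncated
  normals over their plausible ranges; all are constant within a sample.
* **Raw sweeps.** `emit_raw_sweeps()` inverts sweep processing so the
  extraction stage can be exercised end to end. A sweep pair encodes a
  row only through $f_s$ and $\Gamma$: extracted $\Delta f$ and
  $\Delta\Gamma$ reproduce the row, while extracted $\eta$ reproduces
  the *inversion of the row's* $\Delta f$ — the generated $\eta$
  additionally carries the independent per-sample biology term and is
  not recoverable from a single sweep.

**What the generator does not emulate:** temporal drift across the
5-minute acquisition (points are stationary and exchangeable within a
repeat), anticoagulant chemistry (tubes differ only through their class
statistics and clustering calibration), and the joint distribution of
clinical covariates with the sensor features (covariates are drawn
independently given the class). Passing tests on these cohorts therefore
demonstrates properties of the *pipeline* under a faithful statistical
geometry — not clinical performance on real fluids.

## 4. Group statistics

`mann_whitney_u()` computes $U$ by midranks and the two-sided p-value by
exact enumeration of all labelings when $n_1 + n_2 \le 12$, otherwise by
the normal approximation with tie correction and a continuity correction
of $1/2$ toward the mean. Exhaustive enumeration shows the approximation
is within 0.02 of exact for equal group sizes 5–6 and within 0.0305 at
size 4 (worst case $U = 4$) — an intrinsic limit of the approximation
that the tests document rather than hide.

`roc_auc()` computes the AUC as the pair-concordance probability via
midranks, with the Hanley–McNeil standard error
($Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$) and a Wald 95% CI clipped to
$[0,1]$. The positive class (infectious) and orientation (higher score =
more positive) are fixed; an anti-predictive feature such as the
viscosity (published AUC 0.42) is reported below 0.5, never flipped.
`summary_table()` defaults to per-sample aggregation (means of a sample's
rows) for the tests and ROC: repeated measurements of one fluid are not
independent observations, and the published standard errors (~0.04–0.05)
are consistent with sample-level rather than point-level n. Point-level
mode is available for comparison.

## 5. Classification workflow

* **Splits.** 70/15/15 by row ("point" mode) with test and validation
  sizes rounded up — the convention that yields 3480/746/746 from 4972
  rows and 3672/788/788 from 5248, matching the test-set sizes implied by
  every published unbalanced confusion matrix (746 and 788). The
  "grouped" mode applies the same rule to whole samples, the leakage
  control. SVM and RF train on 85/15; the 85/15 split reuses the same
  seeded shuffle, so every model is evaluated on the identical held-out
  15% (a paired comparison; with independent shuffles the model ordering
  is dominated by test-set composition noise).
* **Balancing.** Random oversampling of the minority class to parity,
  applied *before* splitting by default — the published balanced test-set
  sizes (1142, 1241) can only arise that way — with the caveat that
  duplicated minority rows then appear on both sides of the split; this
  is reported, not silently repaired.
* **Scaling.** Median/IQR robust scaler (type-7 quantiles), fitted on
  training data only. No clipping to $[0,1]$ is applied: a quantile
  scaler has unbounded range, and the description of scaling "between 0
  and 1" is taken as loose phrasing rather than a min–max post-step.
* **MLP.** Input (3 features) → one or two 50-unit rectified-linear
  layers → 2-unit softmax; categorical cross-entropy (the standard
  companion of a softmax output, the loss not being published); Adam with
  step size $10^{-3}$ (the framework default implied by naming the
  optimizer alone), batch 16, exactly 100/200/300 epochs, no early
  stopping; per-epoch training and validation accuracy/loss history.
  Written directly on matrix operations — the networks are tiny and the
  implementation is fully seeded (initialization and batch shuffling).
* **SVM.** Linear kernel, penalty $C = 1$, squared-hinge loss, solved in
  the primal by L-BFGS (the objective is smooth and convex); decisions by
  the sign of the decision function. Implemented in-package because the
  available SVM libraries implement the plain hinge; the test suite
  cross-checks decisions against a reference linear SVM on separable and
  near-separable data.
* **RF.** 2171 trees, Gini impurity, bootstrap sampling, depth cap 200,
  minimum node size 1 (equivalent to a minimum split of 2 observations),
  single-threaded and seeded, via `ranger`. The published hyperparameters
  are used as fixed constants; their original grid search is out of
  scope.
* **Evaluation.** Confusion matrices use the inflammatory-positive
  orientation (TP = inflammatory correctly predicted). Accuracy is
  reported at full precision plus two 2-decimal renderings: rounded
  (half-to-even) and truncated. Recomputing accuracy from all 24
  published confusion matrices shows the published grid matches the
  *truncated* rendering in 24/24 cases and the rounded one in only 10 —
  so truncation is what `verify_printed_tables()` matches on, while
  flagging the one scenario whose cells total 1242 against its group's
  1142-row test set.

## 6. Numerical and reproducibility choices

One global seed derives all stage seeds by hashing the stage name
(`derive_seed()`), so adding a stage never perturbs earlier draws; every
seeded function restores the caller's RNG state. Quantiles are type 7
(R's default linear interpolation) throughout. The exact Mann–Whitney
path enumerates $\binom{n}{n_1}$ labelings (at most 924 at the size-12
limit). Degenerate inputs fail loudly: zero IQR names the offending
feature, single-class training sets are rejected, extraction errors name
the sweep that caused them.

Problem sizes in the test suite are the study's own (4972/5248-row
cohorts, the full six-setting network grid at 100–300 epochs); the
distribution-recovery checks use a 10⁵-row cohort (2000 samples per
class, 25 points each), where class-marginal means and SDs are recovered
within 3%.

## 7. Known limitations

* The viscosity feature depends on one calibrated density; absolute
  viscosities for the non-calibrating classes carry a few-percent bias
  by construction (the published tables are mutually inconsistent under
  any single density).
* The two `between_sample_fraction` defaults are calibrated to published
  accuracy bands, not measured from raw data; conclusions about *how
  much* point-split accuracy exceeds grouped-split accuracy on real
  fluids should come from real repeats.
* The cohort's 33/28 samples make sample-level statistics (per-feature
  AUCs, Mann–Whitney p-values) strongly seed-dependent — as they are in
  a real study of this size; distribution-level claims are tested on
  large generated cohorts instead.
* The MLP is a faithful small dense network, not a deep-learning
  framework: no GPU, no callbacks, no regularization beyond what the
  published configuration specifies (none).
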