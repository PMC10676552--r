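---
title: "Modeling plasma protein binding from wide descriptor tables"
author: "ppbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling plasma protein binding from wide descriptor tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppbnet)
```

## The problem

The plasma protein-bound fraction fb of a drug is a dimensionless number
in [0, 1]: the bound portion is pharmacologically inactive, so fb governs
the free concentration, clearance and dosing. Measuring it is slow and
expensive; predicting it from structure is a classic QSAR task. The raw
material is a wide table of computed molecular descriptors — typically a
few hundred compounds against 1000+ columns of constitutional counts,
topological indices, autocorrelations, 3D signals and fragment counts —
in which most columns are uninformative, redundant, or both. `ppbnet`
implements a complete, seeded, auditable pipeline from such a table to a
validated neural-network model with an explicit applicability domain.

## Descriptor filtering

Five screens run in a fixed order; each one logs exactly which columns it
removed and the diagnostic value that condemned them, so the reduction is
reviewable after the fact.

1. **Constant** columns (min = max) carry no information.
2. **Quasi-constant** columns, identified by the 25th percentile equalling
   the 75th percentile. Quantiles are computed by linear interpolation
   between order statistics (R's default, type 7), fixed so the rule is
   reproducible across platforms.
3. **Low relative dispersion**: RSD = s/|mean| < 0.05, with the sample
   (n − 1) standard deviation. A column with mean exactly zero is kept
   (its RSD is effectively infinite) — the convention is recorded in the
   stage log.
4. **Pairwise correlation**: while any pair has |R| > 0.75, the worst pair
   is taken and the member with the larger mean absolute correlation to
   all remaining columns is dropped (ties toward the later column). The
   absolute value matters: an anti-correlated duplicate is exactly as
   redundant as a correlated one. The procedure is deterministic, and
   each removal records its partner and the offending |R|.
5. **Variance inflation**: VIF_i = 1/(1 − R_i²), with R_i² from the
   regression of descriptor i on all others, computed as the diagonal of
   the inverse correlation matrix (with a per-column least-squares
   fallback when that matrix is not positive definite; exact collinearity
   yields +Inf rather than an error). Columns with VIF > 5 are removed
   iteratively, worst first, recomputing after each removal — one-pass
   removal can strand inflated columns, whereas the iterative rule
   guarantees every survivor ends at VIF ≤ 5.

When the pipeline drives the cascade, all filter statistics are computed
on the modeling rows only (training + internal validation) and the column
selection is then applied to everything, so the external set can never
influence a threshold. The VIF stage requires more modeling compounds
than surviving columns; if a dataset is too small the run aborts there
with an identifiability error rather than returning meaningless factors.

## The network and its trainer

The regression model is a single hidden layer of k tanh units with an
identity output,

$$fb = \sum_{j=1}^{k} w2_j \tanh\Big(\sum_{i=1}^{p} x_i w_{ij} + b_j\Big) + b.$$

Inputs are standardized per descriptor (mean 0, sd 1, fitted on training
rows only) to keep the tanh units away from saturation; the target stays
on its natural [0, 1] scale. Weights are initialized uniformly within
±1/√fan-in under a caller-supplied seed.

Training minimizes the sum of squared residuals by Levenberg–Marquardt:
the damped Gauss–Newton update $(J^TJ + \lambda I)\delta = J^T r$ with the
analytic Jacobian, λ starting at 10⁻³, divided by 10 on accepted steps and
multiplied by 10 on rejected ones. Accepted-step training error is
therefore monotone non-increasing. Training stops on a relative
improvement below 10⁻¹⁰, a vanishing gradient or step, a damping blow-up
(the search has stalled), or 200 iterations — all configurable.

These networks usually carry more parameters than there are training
compounds, and unregularized Levenberg–Marquardt will interpolate the
training set in a few dozen iterations. The trainer therefore supports
**validation-based early stopping**, the standard regularizer for this
architecture: after every accepted step the validation MSE is evaluated,
the parameters at the validation minimum are remembered, and training
stops after six consecutive accepted steps without validation improvement.
The returned network is the validation-best iterate. The pipeline always
trains in this mode; `train_lm()` without a validation set runs plain
Levenberg–Marquardt, which the numerical tests rely on.

### Hidden-layer growth

The hidden-layer size is chosen by a growth search: start at k = 5, train
to convergence, append 5 freshly seeded neurons to the trained network
(previous weights retained) and resume, up to k = 50. The search stops
early once the validation MSE has been worse than the best seen for two
consecutive sizes. For each size the trace records R over train +
validation, training R², validation Q², and validation MSE; the selected
size minimizes validation MSE, with ties broken toward larger Q², then
larger training R², then smaller k. A cold-start mode (fresh
initialization at every size) is available via
`pipeline_config(warm_start = FALSE)` for comparison. Per-size seeds are
derived deterministically from the master seed, so the whole search is
reproducible bit for bit.

## Validation statistics

For any (observed, predicted) pairing the battery reports SS (total sum of
squares about the observed mean), RSS, R² = 1 − RSS/SS, adjusted R²,
Pearson R, PRESS (squared prediction error on data not used for fitting),
Q² = 1 − PRESS/SS, MSE, RMSE and MAE. Q² is referenced to the evaluation
set's own mean by default; a training-referenced SS can be supplied
explicitly since conventions differ between groups. Q² may legitimately be
negative — a model worse than predicting the mean — and is never clipped.
The robustness screen is the gap R²(train) − Q²(validation): a gap above
0.3 flags an overfit model. The pipeline evaluates the gap on the internal
validation Q² and reports the external Q² separately.

## Applicability domain

All four methods are calibrated on the training rows and applied to
queries in the filtered, shared-standardized descriptor space:

- **PCA bounding box** — inside iff every retained principal-component
  score lies within the training [min, max] on that component. The number
  of components defaults to those explaining 95% of training variance.
- **Centroid distance** — inside iff the Euclidean distance to the
  training centroid does not exceed the 95th percentile of the training
  rows' own centroid distances.
- **kNN (k = 5 and k = 25)** — inside iff the mean distance to the k
  nearest training rows does not exceed the 95th percentile of the
  training rows' own leave-self-out mean kNN distances. Queries are scored
  against all training rows; self-exclusion applies only to calibration.
- **Leverage diagnostic** — h = x(XᵀX)⁻¹xᵀ on the intercept-augmented
  training design, warning threshold h* = 3(p+1)/n; combined with the
  standardized prediction residual it labels queries in-domain, good
  leverage (far but well predicted), bad leverage, or outlier
  (|standardized residual| > 3). The residual scale defaults to the
  training RMSE when the pipeline calls it.

A caveat worth knowing: the bounding-box verdict tightens rapidly with the
number of retained components, since each component contributes an
independent chance of falling outside the training range. On real
descriptor data, which is strongly collinear, the 95%-variance rule keeps
few components and the box behaves like the other methods. On this
package's synthetic data the post-filter columns are nearly isotropic by
construction, the rule keeps ~45 components, and the box classifies many
same-distribution queries as outside. That is a property of the rule on
isotropic data, not a miscalibration; `pipeline_config(n_components = m)`
pins the count when a different trade-off is wanted.

## The synthetic-data generator

`synthetic_spec()` describes a dataset by the column roles the filter
cascade must handle; `generate_dataset()` builds it under a seed and
returns a ledger naming every column's role, which the tests assert
against exactly. The defaults emulate a 277-compound, 1666-descriptor
study:

| role | columns | construction |
|---|---|---|
| informative | 15 | i.i.d. standard normal; drive the response |
| constant | 50 | one drawn value each |
| quasi-constant | 50 | 95% one value, 5% a shifted value |
| low-RSD | 100 | mean 50–200, sd 0.1–2% of mean |
| correlated blocks | 10 × 5, ρ = 0.9 | shared latent factor |
| multicollinear groups | 5 × (3 parents + 1 child) | child = parent sum + N(0, 0.05) |
| redundant families | 8 × 172, ρ = 0.85 | shared latent factor |
| independent noise | 5 | i.i.d. standard normal |

The latent-factor construction (x = √ρ·f + √(1−ρ)·e) gives the target
pairwise correlation at O(n·d) cost, which matters at d = 1666. The
redundant families are the device that reproduces the dimensionality
collapse of real descriptor software, where whole categories of
descriptors measure the same underlying property: the cascade takes the
default matrix from 1666 columns to ~53, close to the scale real studies
report, with the VIF stage entered at a width safely below the compound
count.

The response is fb = clip₀₁(logistic(g) + ε), where g is itself a small
tanh network over the informative columns (topology 15-10-1),
standardized to sd 2 before the squash, and ε is N(0, 0.02²). Two choices
deserve explanation:

- **The squash**: a bound fraction saturates physically — past some point
  additional affinity changes fb very little — so a logistic link over a
  latent index is the natural functional form, and it guarantees the
  noiseless response lies in (0, 1).
- **The weight scale** of the true network is 1× the fan-in
  initialization, making g a mildly nonlinear index rather than a deeply
  saturated one. This is deliberate calibration: the generator's purpose
  includes demonstrating that the full pipeline can recover a planted
  signal with external Q² above 0.9 at the 277-compound scale, the
  property-based analogue of the external validation a real study reports.
  With strongly saturated truth networks that ceiling is not reachable at
  this sample size with ~38 irrelevant surviving columns, for any trainer —
  the failure is sample complexity, not implementation.

What the generator does **not** emulate: real descriptor semantics and
their heavy-tailed, discrete and block-structured marginals; correlation
between descriptors and the noise; informative columns that are themselves
mutually correlated; and measurement error structure in fb beyond additive
Gaussian noise. Passing tests on this data therefore demonstrate the
pipeline's statistical machinery — exact filtering, trainer correctness,
honest validation, calibrated domain methods — not chemical validity of
any particular fitted model.

## Numerical choices and degenerate inputs

- Quantiles everywhere are type 7 (linear interpolation), stated where
  they matter (quasi-constant screen, AD percentiles).
- Correlation-screen ties (equal mean absolute correlation) drop the later
  column; VIF ties remove the later column. Both are documented so column
  permutations change at most which member of a redundant group survives,
  never the survivor counts.
- `compute_vif` prefers the Cholesky route (fast, O(p³) once) and falls
  back to per-column rank-revealing least squares when the correlation
  matrix is near-singular; exact collinearity reports +Inf.
- The LM normal equations are solved by Cholesky with the damping added;
  a singular system simply raises λ and retries, it never crashes.
- Degenerate targets (constant y) drive the network to the constant with
  MSE → 0; constant observed vectors are rejected by the metric battery
  (SS = 0 has no meaningful R²).
- Scaling a constant descriptor would divide by zero; the scaler
  substitutes scale 1 for zero-sd columns (such columns cannot reach the
  model anyway — the cascade removes them).
- Run reports are serialized without timestamps and with full numeric
  precision, so identical inputs + config + seed give byte-identical
  JSON; stage payloads are recorded by a deterministic numeric
  fingerprint (dimensions and value summaries at 15 significant digits).

## Problem sizes used by the tests

The test suite exercises the cascade and the recovery property at the full
277 × 1666 reference scale (each such run takes seconds), the trainer
contracts on networks with p ≤ 8 and the growth band on 300 + 80 samples
over 10 seeds, the applicability-domain calibration on 400 training / 120
query points in 8 dimensions, and determinism on a reduced 120 × 145
dataset — sizes chosen so each property is measured with comfortable
statistical margin while the whole suite stays quick.

## Known limitations

- Holdout splitting is a single random partition; k-fold rotation and
  y-randomization are out of scope.
- The trainer is dense and single-threaded; at p ≈ 50 and k = 50 a full
  growth search is seconds-to-minutes, but the O((kp)³) factorization
  makes hidden layers beyond a few hundred neurons impractical.
- The applicability-domain suite implements the four geometric methods
  plus leverage; kernel-density and probabilistic estimators are not
  included.
- Descriptor computation itself (SMILES processing) is explicitly outside
  the package: the pipeline consumes a numeric table.

## A minimal session

```{r example, eval = FALSE}
spec <- synthetic_spec(seed = 42)
d    <- generate_dataset(spec)
run  <- run_pipeline(d$x, d$fb, pipeline_config(seed = 42))
print(run)
run_report_json(run, "run-report.json")
```
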