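---
title: "Distance-preserving feature-to-image maps: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-preserving feature-to-image maps: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refinedmap)
```

## The problem

Convolutional networks exploit spatial locality: nearby pixels are
processed by shared kernels. Tabular scientific data — molecular
descriptors of a drug, expression of a gene panel — have no such order;
writing a feature vector row-by-row into a matrix produces an image whose
neighbourhoods are meaningless. `refinedmap` constructs an *injective*
assignment of the p features to pixels of a compact square grid such that
pixel distances approximate feature-space distances. Each sample's vector
then renders as an image whose local patches carry statistically related
features, and ordinary CNNs become applicable to the table.

The pipeline has four stages:

1. **Observed distances.** Each feature is a point in sample space (a
   column of the n x p table); `featureDistanceMatrix()` computes the
   p x p Euclidean distance matrix between columns. Features are first
   filtered (drop any with more than 10% zero-or-missing entries) and
   min-max normalized to [0, 1] — values are never imputed.
2. **Bayesian metric MDS on the unit square.** Latent 2D locations
   s_1..s_p in [0,1]^2 are inferred from the observed distances d under a
   truncated-normal likelihood
   d_jk ~ N(delta_jk, sigma^2) I(d_jk > 0), with
   delta_jk = ||s_j - s_k||, a uniform prior on locations and an
   inverse-gamma IG(a, b) prior on sigma^2 (a > 2, b > 0). The
   unnormalised log posterior is
   `-(q/2 + a + 1) log sigma^2 - SS/(2 sigma^2) - sum log Phi(delta/sigma) - b/sigma^2`
   with q = choose(p, 2) and SS the residual sum of squares. Locations are
   sampled by Metropolis-in-Gibbs; sigma^2 by its approximate inverse-gamma
   conditional. The *posterior mode proxy* — the visited state of maximal
   log posterior — is the point estimate.
3. **Tessellation.** The unit square is cut into the smallest square grid
   with at least p pixels (side `ceiling(sqrt(p))`; 672 features give a
   26 x 26 image) and each feature takes the pixel containing its
   location, collisions resolved deterministically to the nearest free
   pixel.
4. **Hill climbing.** Because the likelihood identifies locations only up
   to rigid motions, and binning is lossy, a greedy local search sweeps
   the grid in row-major order, exchanging each feature with its 8
   neighbouring pixels whenever that strictly lowers the cost
   `sum_{j<k} | pixelDist(j,k) - deltaHat_jk |`, where deltaHat is the
   distance matrix induced by the Bayesian point-estimate locations and
   pixel distances are index offsets divided by the grid side (so both
   operands live on the unit square's scale).

`buildRefinedMap()` composes all four stages under one seed.

## Worked example

```{r pipeline}
ds <- simulateDataset(N = 300, P = 36, gamma = 0.7, spuriousFrac = 0.2,
                      seed = 1)
res <- buildRefinedMap(ds@table,
                       bmds = bmdsConfig(nIter = 600, burnIn = 300,
                                         seed = 1))
res
imgs <- vectorsToImages(ds@table, pixelMapOf(res))
imgs
```

The hill-climb report shows the cost drop and, for monitoring, the
Pearson correlation between pixel distances and the target distances
before and after refinement.

## Parameters that matter

* `a`, `b` (inverse-gamma prior on the noise variance; defaults 3 and 1,
  dimensionless). The model requires a > 2 so the prior variance exists;
  with hundreds of features the likelihood dominates and the defaults are
  uninformative in practice.
* `nIter`, `burnIn`, `thin` (sweeps; defaults 2000 / 1000 / 10). One sweep
  updates every location once and sigma^2 once. Maps stabilise quickly
  because only the MAP state feeds the downstream stages; posterior draws
  (`posteriorDrawMaps()`) are retained for training-set augmentation.
* `proposalSd` (default 0.05 in unit-square units): the Metropolis step.
  0.03-0.2 mixes well for p from a handful to a few hundred.
* `maxSweeps` (default 50): hill-climb budget; strict-improvement
  acceptance guarantees termination, typically far earlier.
* Training defaults: Adam with learning rate 1e-4, batch 128, dropout
  keep 0.7, early stopping on validation loss with patience 20 and
  best-weight restore. The learning rate sits inside the range normally
  searched for this task family; small images and small samples benefit
  from raising it to ~1e-3.

## Numerical choices

* **Distance scale.** Observed column distances can exceed the unit
  square's diameter, so `buildRefinedMap()` rescales the distance matrix
  to maximum 1 before embedding; the likelihood is otherwise asked to
  compare distances that no configuration in [0,1]^2 can realise.
* **Initialisation.** Classical MDS (Torgerson) seeds the sampler;
  configurations already fitting the square are translated, not rescaled,
  so realizable geometry is preserved exactly. Isomap (via vegan),
  locally linear embedding and Laplacian eigenmaps — both computed
  directly from the distance matrix — and uniform-random placement are
  available as ablation initialisers, with or without the Bayesian stage.
* **Boundary handling.** Metropolis proposals are reflected at the unit
  square's walls rather than rejected, keeping the uniform support exact
  without wasting proposals.
* **sigma^2 conditional.** The truncation term `sum log Phi(delta/sigma)`
  is kept in the Metropolis ratio but dropped from the variance
  conditional (its large-q inverse-gamma approximation), which is how the
  model is normally estimated; with q = choose(p, 2) the term is
  negligible there.
* **Collision ties.** Nearest-free-pixel search expands Chebyshev rings
  and scans each ring in row-then-column order: deterministic, local, and
  independent of feature order.
* **Constant features** normalize to zero rather than erroring, so inert
  descriptors cannot abort a pipeline. Degenerate all-zero distance
  matrices are an error.
* **Hill-climb moves.** "Exchange with a neighbouring feature" is read as
  single greedy swaps over the 8-connected neighbourhood with strict
  improvement; multi-feature permutations inside a 3 x 3 patch would be a
  natural extension but are not implemented. The absolute-difference cost
  is the optimisation target; the correlation is only reported.

## The synthetic benchmark

`simulateDataset()` generates the study conditions every distance and
model-comparison check runs under: N samples of P features drawn from a
zero-mean Gaussian process over a lexicographic feature ordering with
stationary covariance gamma^|i-j| (default gamma 0.7), realised exactly by
Cholesky factorisation. A stated fraction of features (20/50/80% in the
benchmark grid) is spurious — weight exactly zero — and the remaining
weights are standard-normal draws resampled away from zero; the weights'
scale is irrelevant because targets y = Xw are min-max normalized to
[0, 1]. No noise is added by default (a `noiseSd` option exists). Features
are also min-max normalized so they can feed image rendering directly.

What this emulates: smoothly correlated predictor panels with irrelevant
members and a linear signal. What it does not: heavy-tailed or zero-
inflated marginals, nonlinear responses, batch structure. Passing tests
on this generator therefore demonstrate the *mapping machinery* — distance
preservation, spurious-feature tolerance, the relative advantage over
random pixel arrangements — not performance on any particular assay.

Problem sizes used by the shipped checks were chosen for a single CPU:
the sampler/mode cross-check runs at p = 3 against an exhaustive
grid search; distance-preservation comparisons at P = 100, N = 600 over
five seeds; the model comparison at N = 1000, P = 100 with 80% spurious
features over three seeds, 60 epochs per model with a 3 x 3 / stride-1
version of the regressor stack (the 7 x 7 / stride-2 default cannot fit a
10 x 10 image). Larger P and N only make the mapping easier to
demonstrate.

## The CNN engine

No external deep-learning runtime is required: the package ships a
self-contained engine (valid-mode strided convolution via im2col, batch
normalization, ReLU, dropout, dense layers, Adam, early stopping) with
analytic gradients verified against numerical differentiation in the test
suite. Three published architectures are encoded: a sequential regressor
(two 64-kernel 7 x 7 stride-2 conv blocks, dense 256/64, dropout keep
0.7, linear head), a sequential classifier (16/32 7 x 7 and 64 3 x 3
conv blocks, dense 256/64, sigmoid head), and a two-arm hybrid for
cell-line/drug image pairs (60 5 x 5 stride-1, 72 6 x 6 stride-2,
72 5 x 5 per arm — stride 2 on the cell arm, 1 on the drug arm —
concatenated into dense 305/175). Evaluation-mode prediction uses running
batch-norm statistics, so predictions are independent of batch size.

## Evaluation toolkit

Regression: NRMSE (model RMSE over mean-predictor RMSE), NMAE, Pearson
correlation, and the prediction bias. Bias carries two conventions that
are *not* algebraically equivalent, and both are exposed: the vector-angle
form `theta = acos(y'(y - yhat) / (||y|| ||y - yhat||))`, bias =
tan(theta); and the residual-trend form, the least-squares slope of
residuals on observations (zero for trend-free residuals). For unbiased
noisy predictions the slope convention tends to 0 while the vector angle
tends to 90 degrees; the slope convention is therefore what the
bias-correction utilities monitor, while `biasAngle()` defaults to the
vector-angle formula as printed.

Model comparison uses paired bootstrap machinery: gap statistics (each
replicate resamples the test set, computes the model's metric and a null
model's — predictions drawn from the training-response distribution —
then 1-D k-means with k = 2, initialised at the two distribution means,
splits each pooled metric distribution; the centroid distance is the
gap). A subtlety the tests encode: k-means always splits a pooled sample,
so even model-equals-null comparisons leave a residual gap of roughly the
within-distribution spread; gaps are interpreted relative to that floor.
Robustness is the fraction of replicates in which one model strictly
beats another. Confidence intervals: bootstrap percentile intervals for
regression metrics and the normal-approximation binomial proportion
interval (Wilson as an option) for classification. Paired classifiers are
compared by McNemar's test (exact binomial below 25 discordant pairs,
continuity-corrected chi-square otherwise).

Bias correction (`bc1Correct()`) fits the linear residual trend
eps = alpha + beta y on a set with known observations. At test time y is
unknown, so the fitted trend is inverted through the prediction: solving
y = yhat + alpha + beta y gives the implied observation
(yhat + alpha)/(1 - beta), which is the corrected prediction. This
inversion is this package's reading of test-time application; with the
observed regressor (validation data) the correction zeroes the fitted
residual slope exactly.

Stacking (`stackPredictions()`) combines models with weights on the
probability simplex (nonnegative, summing to one), fitted on validation
predictions. The weights solve the simplex-constrained least-squares
problem exactly (by support enumeration — model counts are small) rather
than rescaling an unconstrained nonnegative fit, because only the
constrained optimum guarantees the stack never fits the validation set
worse than its best member.

## Known limitations

* The hill climb is a local search: it certifies 1-swap local optimality,
  not global optimality of the assignment (global QAP-style solvers are
  out of scope).
* Locations are identifiable only up to rigid motions; maps from
  different seeds can differ by an automorphism while inducing equivalent
  images for a CNN.
* The MAP proxy (best visited state) is a mode estimate only as good as
  the chain's coverage; very small p gives broad posteriors where long
  chains are needed for a stable mode.
* Rectangular grids, multi-channel images and spatial smoothing of the
  rendered images are not implemented.
* The engine is CPU-bound plain R: suitable for the package's benchmark
  scale (thousands of samples, grids up to a few tens of pixels per
  side), not for large-scale screens.
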