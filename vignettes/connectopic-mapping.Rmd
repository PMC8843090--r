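---
title: "Connectopic mapping: model, assumptions and design choices"
author: "conngrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectopic mapping: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conngrad)
```

## The model

Connectopic mapping asks how a region's functional connectivity with the
rest of the brain changes *across* the region, rather than treating the
region as a homogeneous parcel. Given a 4D BOLD series, a region of
interest (ROI) and a brain mask, the pipeline is:

1. **Time-series extraction.** The ROI voxels form a `t x V` matrix `A`
   and all remaining in-brain voxels a `t x W` matrix `B`; columns are
   demeaned over time. Pearson correlation downstream is
   scale-invariant, so no variance normalization is applied.
2. **Lossless reduction.** `B` is reduced by singular value
   decomposition to its orthonormal temporal basis at numerical rank
   (singular values above `max(t, W) * eps * sigma_1`). Fingerprints
   computed against the components carry the same correlation geometry
   as fingerprints against all `W` columns.
3. **Connectivity fingerprints.** Each ROI voxel is correlated with
   every retained component, one fingerprint (row of `C`) per voxel.
4. **Similarity.** Fingerprint similarity uses the eta-squared
   coefficient: one minus the ratio of within-pair to total sum of
   squares, 1 for identical profiles. It is symmetric, lies in [0, 1],
   and is invariant to a *joint* constant shift of both profiles (but
   not to shifting one of them).
5. **Laplacian eigenmaps.** A graph over ROI voxels is weighted by the
   similarity matrix (diagonal zeroed; dense by default, optionally a
   symmetrized k-nearest-neighbour graph). Solving `L v = lambda D v`
   and discarding the trivial constant eigenvector yields the
   connectivity modes in ascending eigenvalue order. We index modes from
   0: the "second-order" mode of a striatal analysis is the third
   nontrivial eigenvector.

Subject modes are sign-ambiguous; `align_mode()` inverts a mode when it
correlates negatively with a group reference. Group-level modes come
from the element-wise average of individual similarity matrices.

## Trend surface models

A mode is a smooth spatial field, so it is summarised by regressing it
on per-axis polynomial functions of the voxels' world (mm) coordinates:
columns `x^1..x^d, y^1..y^d, z^1..z^d` — `3d` coefficients, no
cross-terms, no intercept. A degree-2 model has 6 coefficients and a
degree-4 model 12. Two numerical choices matter:

* **Coordinate normalization.** Each axis is affinely mapped to
  [-1, 1] before powering; raw mm coordinates raised to the 4th power
  are catastrophically ill-conditioned. The normalization is computed
  once per ROI mask and reused for every subject so coefficients are
  comparable across subjects.
* **Centring.** The basis has no intercept, so the fit centres both the
  response and the design columns; the mode mean is restored on
  reconstruction. Centring only the response would leak the intercept
  into the residual, because monomial columns have nonzero means.

The fit is Bayesian linear regression with an isotropic Gaussian prior
on the weights (precision `alpha`) and Gaussian noise (precision
`lambda`) — two hyperparameters controlling the data and noise
variance. They are set by empirical Bayes: maximizing the closed-form
log marginal likelihood over `(log alpha, log lambda)` with an
analytic-gradient quasi-Newton optimizer (L-BFGS-B) from three spread
starts. Hyperparameters are confined to `[1e-14, 1e14]`: a noiseless
response drives the noise precision to the boundary, where the solution
is ordinary least squares, which is the correct limit. At any fixed
`(alpha, lambda)` the posterior mean equals the ridge solution with
penalty `alpha / lambda`; the test suite verifies this against the
closed form and verifies stationarity of the evidence at the returned
optimum (a +/-10% perturbation of either hyperparameter never increases
it).

**Degree selection.** Models of degree 2–5 are compared by a scree
rule on variance explained (averaged over subjects when several are
supplied). We operationalize the elbow as: choose the largest degree
whose gain over the previous degree exceeds `tau = 0.05` of the
variance still unexplained at the previous degree (the smallest
candidate is compared against a null model explaining nothing). A flat
profile with no qualifying step falls back to the smallest candidate
with a warning. `tau` is exposed; 0.05 makes the rule insensitive to
the ~`3/V` in-sample gain that three spurious extra regressors
contribute.

## Group statistics

* **Spatial correlation** of a mode with a scalar density map is plain
  Pearson over ROI voxels. Its p-value ignores spatial autocorrelation
  (flagged in the result); the complementary **coefficient-space
  correlation** across the concatenated trend-surface coefficients of
  both maps avoids that inflation because the coefficients are compact
  orthogonal summaries.
* **Quality filtering** keeps subjects whose mode correlates with the
  group reference strictly above `r_min` (default 0.5).
* **ICC(2,k)** — two-way random effects, absolute agreement, average
  measures — is computed from the ANOVA mean squares, with a percentile
  bootstrap over subjects for the confidence interval. The quantity
  submitted to the ICC is each trend-surface coefficient (summarised by
  the mean across coefficients per ROI); voxel-wise mode values can be
  submitted instead by passing the mode matrices directly.
* **Within/between permutation test**: within-subject session-1 to
  session-2 mode correlation versus the mean across different-subject
  pairs; the null permutes session-2 labels; the add-one estimator
  `(1 + #{perm >= obs}) / (1 + n_perm)` keeps p strictly positive.
* **Omnibus tests.** Group differences: likelihood-ratio test of a
  logistic regression of group on all coefficients. Continuous
  outcomes: linear-model LR, `X^2 = n log(RSS_null / RSS_full)`. In
  both cases the reported statistic is the LR chi-square, but the
  default p-value uses a finite-sample F-calibrated reference: the LR
  statistic is mapped through the nested-linear-model identity
  `X^2 = n log(1 + df F / df2)` and referred to `F(df, df2)`. For the
  linear model this *is* the exact null distribution; for the balanced
  logistic omnibus it removes the O(1/n) anti-conservatism of the
  chi-square reference (at n = 60, df = 6 the raw chi-square rejects at
  ~0.07 nominal 0.05; the calibrated reference is uniform within
  Monte-Carlo error — the test suite checks both the rejection rate and
  Kolmogorov–Smirnov uniformity). The asymptotic chi-square p is kept
  as `p_chisq`. Perfect separation is detected and flagged.
* **Post-hoc Pearson correlations** per coefficient are deliberately
  uncorrected — they are descriptive follow-ups to a significant
  omnibus. Family-wise control uses `bonferroni()` (e.g. 0.05/4 =
  0.0125 for two groups x two subregions).

## The phantom generator

Real resting-state data offer no ground truth, so validation runs on
phantoms that plant exactly the structure the method assumes:

* **Planted gradients** are low-order polynomials of world coordinates
  within each cuboid ROI, Gram–Schmidt orthogonalized and unit-normed.
* **BOLD synthesis.** A set of network time courses (smoothed Gaussian
  series — the analysis only consumes second-order statistics, so no
  hemodynamic realism is attempted) is mixed into each ROI voxel with
  Gaussian-kernel weights in gradient-value space, so fingerprints vary
  smoothly along the planted gradients — precisely the property
  Laplacian eigenmaps recovers. Non-ROI voxels each carry one network's
  series. White noise enters at a configurable signal-to-noise ratio
  (`snr = 5` default; `0` gives pure noise, `Inf` noiseless).
* **Anchor layout and gradient scales.** Mixing anchors sit on a
  regular grid covering the gradient-value range (a random layout
  leaves coverage holes that degrade recovery of the second mode), with
  kernel width 1.4 in units of the leading gradient's spread. Gradient
  `k` is scaled by `1 - 0.15 (k - 1)`: extents are comparable, so every
  planted gradient appears among the leading modes, yet strictly
  decreasing, so mode order is deterministic; keeping every scale above
  half the leading scale prevents a spatial harmonic of gradient 1 from
  overtaking gradient 2 in the eigenvalue ordering.
* **Cohorts.** Subject, session and group variation is injected in
  trend-surface *coefficient* space on a standardized gradient scale
  (field sd 1), so ground-truth effect sizes are exact and the design
  sds read as fractions of the gradient amplitude. Defaults:
  between-subject sd 0.15, within-subject sd 0.05 (per-coefficient ICC
  around 0.9, matching the high test–retest consistency reported for
  such modes); a group effect of 0.1 on each coefficient at n = 30 per
  group gives the binary omnibus high power at the 0.0125
  Bonferroni-corrected level (noncentrality ~ 40 on 6 df) without
  routinely separating. The continuous outcome is a linear coupling of
  the subject's coefficients plus noise. Per-subject random streams are
  separated, so enlarging a cohort never changes existing subjects'
  data.

**What the phantoms do not emulate:** hemodynamics, physiological and
motion artefacts, spatial autocorrelation of noise, non-stationary
connectivity, and registration error. Passing tests therefore establish
the correctness of the algorithms under their own assumptions, not
performance on real scanner data.

## Problem sizes and determinism

Validation uses ROIs of ~343 voxels, 300 timepoints and snr 5 — sizes
at which the dense eigensolvers are exact and runs complete in seconds.
Dense solves keep results fully deterministic; ties in the eigenvalue
spectrum are broken by ascending eigenvalue and a first-significant-
entry sign convention applied before any alignment. All stochastic
steps (simulation, bootstrap, permutation) are driven by explicit
seeds, and identical configurations reproduce bit-identical outputs.

## Worked example

```{r example, eval = FALSE}
scene <- build_scene(gradient_degrees = c(1, 2), snr = 5, seed = 1)
syn <- synthesize_bold(scene, t = 300, seed = 1)
roi <- scene$roi_specs[[1]]
res <- map_subject(syn$bold, roi, syn$brain_mask, n_modes = 2)

# recovery of the planted gradients
G <- scene$planted_gradients[[1]]
cor(res$modes[[1]]$values, G[, 1])
cor(res$modes[[2]]$values, G[, 2])

# summarise mode 0 with a degree-2 trend surface
basis <- build_basis(roi$world_coords, 2)
fit <- fit_blr(basis, res$modes[[1]]$values)
fit$variance_explained

# compare with a density map planted on the same gradient
dens <- roi_values(derive_density_map(scene, transform = "logistic"), roi)
mode0 <- align_mode(res$modes[[1]], dens)
spatial_correlation(mode0$values, dens)$r
coefficient_correlation(fit_blr(basis, mode0$values)$beta,
                        fit_blr(basis, dens)$beta)$r
```

## Known limitations

* The eta-squared similarity is the standard within/total sum-of-squares
  definition; other monotone rescalings of similarity would change the
  similarity scale but, on the phantoms, not the eigenmap ordering.
* Voxel-wise correlation p-values are not corrected for spatial
  autocorrelation (use the coefficient-space correlation when that
  matters).
* The logistic omnibus at 12 coefficients and small n can separate
  perfectly; results are flagged, not suppressed.
* Iterative/sparse eigensolvers are not implemented; ROIs far above
  ~2000 voxels would need them.
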