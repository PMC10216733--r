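---
title: "Hypergraph-regularized temporal sparse CCA with deep subspace reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypergraph-regularized temporal sparse CCA with deep subspace reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Longitudinal imaging-genetics studies ask which genes move together with
which brain phenotypes as a disease progresses. The data are one static
gene-expression view `X` (n samples × q genes) and a sequence of
phenotype views `Y1 … YT` (n samples × p regional gray-matter measures at
T visits). Sparse canonical correlation analysis (SCCA) finds weight
vectors `u` (genes) and `vt` (phenotypes, one per visit) whose projected
scores `X u` and `Yt vt` correlate maximally, with sparsity selecting a
small, interpretable marker set.

This package implements a temporally constrained, hypergraph-regularized
variant of that idea, together with an optional label-guided deep
subspace reconstruction of each view, a coupled latent-factor simulator,
and the evaluation protocols used to validate the method entirely on
synthetic data.

## The model

The fitted model minimizes, over `u` and `V = [v1 … vT]`,

```
- sum_t  u' X' Yt vt                 (negated summed cross-view covariance)
+ lam1 * ||u||_1                     (gene sparsity)
+ lam2 * ||V||_{2,1}                 (row sparsity: a phenotype is in or out
                                      across all visits jointly)
+ lamt * sum_{t<T} ||v_{t+1} - v_t|| (temporal fusion: smooth weight
                                      trajectories across visits)
+ beta1 * (Xu)'  L1 (Xu)             (hypergraph smoothness of the gene
                                      scores over the sample hypergraph)
+ beta2 * sum_t (Yt vt)' L2t (Yt vt) (same for each phenotype view)
```

subject to `||X u|| <= 1` and `||Yt vt|| <= 1`. Setting
`beta1 = beta2 = 0` gives the temporally constrained group-sparse CCA
baseline (`fit_tgscca()`); the full model is `fit_hbtgscca()`.

Two sign conventions circulate for such objectives; we minimize the
*negated* covariance and *add* the hypergraph quadratics, which is the
only convention under which the optimizer rewards correlated scores and
penalizes rough ones. The fused difference norm is the group (L2) norm by
default, coupling whole weight-vector increments between adjacent visits;
an elementwise L1 variant is available via `penalty_config(fused =
"l1")`.

### Hypergraphs over samples

`build_knn_hypergraph()` builds one hyperedge per sample containing the
sample and its k nearest neighbors (Euclidean by default, ties broken by
sample index), so every hyperedge has degree k + 1. The regularizer is
the normalized hypergraph Laplacian
`Lh = I − Dv^{-1/2} H W De^{-1} H' Dv^{-1/2}`, which is symmetric,
positive semidefinite, and annihilates the square-root-degree vector.
Vertices are samples: the quadratic forms above act on the length-n
projected score vectors, encouraging samples that share hyperedges —
i.e. whole neighborhoods, not just pairs — to receive similar scores.
Hyperedge weights default to 1; a heat-kernel weighting (summed
`exp(-d^2 / sigma^2)` to the centroid, with `sigma` the mean pairwise
distance) is available. `k = 5` by default: with the sample sizes this
package targets (tens to a few hundred), smaller k makes the hypergraph
too fragmented to carry neighborhood information and much larger k blurs
it toward the global centering operator.

### The solver

The solver alternates block updates of `u` and `V`:

* candidates come from proximal-gradient (ISTA) descent of the block's
  Lagrangian form, in which the scale constraint appears as the quadratic
  `0.5 ||Xu||^2` (resp. `0.5 ||Yt vt||^2`);
* the `u` candidate is rescaled onto `||Xu|| = 1`; the `V` candidate is
  rescaled by a single common factor so that `max_t ||Yt vt|| = 1` —
  a per-visit rescale would silently undo the temporal fusion that a
  large `lamt` has just imposed;
* a candidate is accepted only if the constraint-form objective above
  does not increase.

The acceptance rule makes the recorded `objective_trace` non-increasing
by construction, whatever the inner solvers do. In the penalty-free case
the block updates reduce to `u ∝ (X'X)^{-1} X' Y v` and its mirror —
the classical alternating-regression power iteration for canonical
correlation — so with all penalties at zero the solver reproduces
textbook CCA (this is verified against `stats::cancor` in the tests).

Two scale metrics are offered for the constraint quadratics.
`scale_metric = "covariance"` (the default) uses `X'X` and `Yt'Yt`: the
penalty-free fit is then exact classical CCA, but the L1 block update is
a lasso *regression* of the phenotype score on the genes, and under
strong inter-gene correlation — precisely the regime a shared latent
signal creates — lasso keeps one representative per correlated group and
zeroes its peers, which is the wrong behavior when the task is marker
*selection* rather than prediction. `scale_metric = "identity"` uses the
diagonal approximation of the standardized covariance and runs the
classic PMA-style alternation: each u step soft-thresholds the
time-averaged sample correlations (so the tuning grid, spanning
0.0001–1, reads directly as a correlation threshold) and is then
normalized. The identity alternation has no monotonicity guarantee for
the reported objective (its trace is recorded for diagnostics and the
loop stops on iterate change); the covariance metric carries the
guarantee. Support-recovery evaluations in this package use the identity
metric with the one-standard-error grid rule; correlation-maximization
benchmarks use the default.

The composite nonsmooth term in the `V` block (row-group plus chain
fusion) is handled by one row-group soft-threshold followed by the exact
proximal operator of the chain group-fused penalty, computed through its
dual as a projection onto per-difference norm balls; the acceptance check
absorbs the error of composing the two proximal maps.

Numerical choices: outer loop at most 100 iterations, stopping when the
relative objective change drops below 1e-5; inner proximal loops 200
iterations at 1e-8 with backtracking (factor 0.5); initialization from
the rank-1 SVD of `X' Ybar` with `Ybar` the time-averaged phenotype
view. Views are column-standardized before fitting; constant columns are
dropped with a warning. An all-zero solution (penalties too large) is
reported in `diagnostics$all_zero` rather than raised as an error, since
it is a legitimate corner of a penalty grid.

## Deep subspace reconstruction

Samples with the same diagnostic label are assumed to lie near a common
low-dimensional subspace. `train_reconstruction_network()` trains a small
tanh autoencoder (default encoder `p → 64 → 32`, mirrored decoder,
full-batch gradient descent with an adaptive step that never lets the
loss increase) jointly with a self-expression matrix `C` that
reconstructs each latent code from the codes of *other* samples with the
*same* label:

```
|| X - g(f(X)) ||_F^2  +  lam_se || f(X) - C f(X) ||_F^2  +  lam_l1 ||C||_1
```

`C` has an exactly zero diagonal and exactly zero cross-label entries —
these are enforced structurally (masked coordinates), not by penalty —
and is refit in closed convex form (coordinate-descent lasso for small
label blocks, an accelerated proximal solver for large ones) every 10
epochs. The reconstructed view is `g(C f(X))`: each sample is replaced by
the decoded combination of its same-label peers, which projects
within-class noise out while preserving the class geometry. Fitting the
self-expression in latent space is the default; `latent_space = FALSE`
runs the linear ablation directly in input space.

The L1 level on `C` is the one tuning knob that matters. At
`lam_l1 = 1` (the default, equal to the self-expression weight) each
sample is expressed by a handful of peers, which is what denoises a view
for clustering; the association pipeline instead passes `lam_l1 = 0.01`,
because aggressive self-expression shrinkage flattens exactly the
per-sample variance that canonical correlation feeds on. Whether
reconstruction happens before or after the train/test split is
configurable; the default reconstructs first, which matches the natural
workflow of a transductive self-expression model (`C` couples all
samples) but does mean train and test are not strictly independent — the
raw-data ablation (`reconstruct_views_flag = FALSE`) quantifies what that
buys.

## The simulator

`simulate_joint_longitudinal()` draws, per sample, a latent factor
`eps ~ N(0, latent_sigma^2)` shared by both views. Signal phenotype
columns of the first visit are `eps * alpha_j + e`, signal gene columns
are `eps * beta_j + e`, with `e ~ N(0, noise_sigma^2)` and the planted
weights drawn from the signed-uniform mixture `U(-1,-0.5) ∪ U(0.5,1)`
(every signal weight bounded away from zero). Non-signal columns are
pure noise and carry a true weight of exactly 0. Later visits follow a
random walk `T[i+1] = T[i] + dV` with i.i.d. `N(0, drift_sigma^2)`
entries, `drift_sigma^2 = 0.1` by default — the drift is read as a
variance, and the same noise realization propagates along the walk
(visits are not re-noised independently). Defaults are n = 200 samples,
p = 90 phenotype features, q = 450 genes, T = 4 visits, unit latent and
noise scales, and half of the features in each view carrying signal; the
latent scale and signal fractions are free parameters of the design and
their defaults are the neutral choices (unit variance, half-and-half).

What the simulator does *not* emulate: spatial autocorrelation between
neighboring brain regions, linkage or co-expression correlation between
genes, non-Gaussian tails, batch structure, or missing visits. Passing
the simulation-based checks therefore says the estimator recovers a
planted sparse, temporally drifting, latent-factor coupling — not that
it is robust to everything real cohort data can do.

`simulate_multisubspace()` plants the complementary structure for the
reconstruction stage: per class an orthonormal basis of a
`subspace_dim`-dimensional subspace, samples as Gaussian coefficient
combinations plus isotropic noise.

## Protocols and problem sizes

The experiment drivers follow a fixed protocol: a single random 4:1
train/test split (no stratification), penalties tuned on the training
split by 5-fold cross-validation scoring mean held-out canonical
correlation across visits, the winner refit on the full training split,
and test-set correlations reported per visit. The tuning range is
`{0.0001, 0.001, 0.01, 0.1, 1}` per penalty; the default grid ties
`beta1 = beta2` and `lam2 = lamt` (125 points), with `full = TRUE`
expanding to the untied 3125. Training-set scoring (the literal
"average of the CCCs" selection) differs from CV scoring only in which
split the correlations are computed on and is available by scoring the
grid table directly.

Grid selection defaults to the CV-score argmax. When the *sparsity
pattern* is the quantity of interest — support-recovery evaluations, for
instance — held-out correlation is nearly flat across several penalty
levels and the argmax picks a density at random; `grid_search(select =
"1se")` applies the usual one-standard-error parsimony rule (the sparsest
model within one standard error of the best CV score).

The packaged validation experiments run at reduced sizes chosen to keep
a full run on a single CPU in minutes: the noise-sweep comparison at
n = 100, p = 30, q = 60 with sigma_e ∈ {1, 5}, reconstruction at 30–40
epochs, and single-point or single-axis grids where the quantity under
study does not depend on the sweep (the direction of the noise effect,
for example, does not require retuning all five penalties per seed).
These sizes are stated in the test and script sources; nothing about the
method changes with scale except runtime.

## Known limitations

* The transductive self-expression matrix means `reconstruct()` applies
  only to the samples the model was trained on; out-of-sample
  reconstruction would need a side-information model for `C`.
* The V-block proximal composition is inexact (two proximal maps applied
  in sequence); the acceptance rule converts that into, at worst, an
  early stop rather than an objective increase.
* With penalties at zero and `T > 1` the objective is a sum of T
  bilinear terms and the alternation finds the dominant shared direction,
  which is only the per-visit canonical direction when the visits agree.
* Cross-validated canonical correlations on small folds are noisy;
  degenerate folds (constant projections) are dropped and recorded as
  `NA` in the grid table rather than imputed.
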