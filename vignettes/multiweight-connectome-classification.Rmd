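---
title: "Classifying multi-weight structural connectomes with a multiple-kernel SVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying multi-weight structural connectomes with a multiple-kernel SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Diffusion-MRI tractography summarizes a subject's white matter as a
network over a fixed parcellation — here the 90 cerebral regions of the
AAL atlas. A region pair is connected when at least one streamline ends
in both regions, and the same anatomical topology can be weighted in
three biophysically different ways: the streamline count (FN), the mean
fractional anisotropy over the voxels of the connecting fibers (FA), and
the mean diffusivity over those voxels (MD, mm²/s). Early neurodegeneration
is expected to lower FN and FA and to raise MD on affected connections,
but any single weighting carries only part of the signal.

`mklconn` implements a classifier that uses all three weightings at once:
the `3 × 4,005 = 12,015` edge weights of a 90-node subject are treated as
features, filtered by a univariate F-score (or a lasso), and fed to a
support vector machine whose kernel is a learned convex combination of one
kernel per network,
`k(x_i, x_j) = Σ_m β_m k⁽ᵐ⁾(x_i⁽ᵐ⁾, x_j⁽ᵐ⁾)` with `β_m ≥ 0`, `Σ β_m = 1`.
The learned `β` tells which weighting carries discriminative information;
the hyperplane coefficients times `β`, intersected across cross-validation
folds, tell which edges.

## Data model

`multiweight_connectome` holds the three `n × n` matrices and enforces the
invariants that make the multi-network reading coherent: symmetry, zero
diagonal, a *shared* binary support, integer FN counts, FA in (0, 1] and
positive MD on the support. `vectorize_cohort` flattens a labeled cohort
into a `feature_table` whose canonical column order is fixed and recorded
as per-column provenance: network blocks FN, FA, MD; within a block the
upper-triangle pairs `(i, j)`, `i < j`, sorted lexicographically with
1-based region indices. The order is arbitrary but must be stable, because
consensus features are reported by column index and region names; the
provenance makes vectorization exactly invertible
(`devectorize_subject`).

Networks can also be built from labeled streamline sets
(`build_networks`): a streamline's first and last voxel determine its
endpoint regions (no dilation or search radius — a streamline ending in
background is dropped and counted), both-endpoints-in-one-region
streamlines are discarded since edges are defined for region *pairs*, and
FA/MD edge weights are means over the set of voxels traversed by all
streamlines of the pair. We deduplicate that voxel set by default (a voxel
visited twice counts once); `voxel_multiset = TRUE` switches to the
visit-count-weighted reading, which is equally defensible — the two
coincide for non-overlapping streamlines.

## The synthetic cohort generator

The study data behind this design are clinical MRI cohorts that are not
redistributable, so the package ships a generator
(`generate_cohort`) that emulates the statistical structure every
downstream stage relies on, and the whole pipeline is tested against it.

* One binary topology at a configurable density (default 0.15, a typical
  deterministic-tractography density at 90 nodes) is shared by all
  subjects, which makes the same-topology invariant hold cohort-wide.
  Real cohorts have subject-specific topologies; `topology_jitter`
  toggles a fraction of edges per subject for robustness experiments.
* Per-edge baselines are drawn once: lognormal FN counts
  (median 30), FA in (0.2, 0.8), MD around `0.7e-3` mm²/s — the physical
  ranges of healthy white matter.
* Subjects add independent Gaussian noise with per-kind between-subject
  SDs (15% of the baseline count for FN, 0.04 for FA, `0.04e-3` for MD),
  and patients additionally receive signed shifts on a chosen edge subset,
  expressed in units of that between-subject SD, so a requested effect of
  1.5 is a 1.5-SD standardized group difference. The default effect
  direction is the degeneration pattern: FN −1, FA −1, MD +1 SD on 12
  edges.
* Values are kept physical afterwards (counts rounded and ≥ 1, FA clamped
  to (0, 1], MD positive); at the default parameters the clamping is
  inactive, so the calibration tests can verify the realized effect size
  against the request.
* One integer seed drives deterministic sub-seeds for topology, affected
  edges, baselines and noise, so each stage is independently reproducible.

What passing tests on this generator do *not* show: robustness to
subject-specific topologies (unless jittered), to site or motion
artefacts, to non-Gaussian heavy-tailed edge noise, or to correlated
edge effects along fiber systems — real cohorts have all of these.

## Feature selection

The F-score of feature *i* is the ratio of the squared deviations of the
two group means from the overall mean to the sum of the two within-group
sample variances (denominators `n± − 1`). It is affine-invariant and
cheap at `p = 12,015`. Degenerate columns are given sentinels rather than
NaNs: constant within both groups with different means (a perfect
separator) scores `+Inf` and ranks first; globally constant scores 0.
Ties rank the lower column index first so reruns are deterministic.

A fraction `f` of features converts to a count `k = max(1, round(f·p))`
over the *pooled* columns of all three networks, so the per-network split
of the selected set is data-driven — which is what lets the consensus
counts differ per network. The alternative (selecting per network) is not
implemented.

The multivariate alternative is a lasso: L1-penalized least squares of
the ±1 labels on standardized features (fitted via glmnet), the penalty
chosen on a 30-point log grid spanning four decades below the smallest
all-zero penalty by fivefold cross-validated squared error; features with
non-zero coefficients are selected, and a fully shrunk optimum falls back
to the smallest penalty with a non-empty selection.

## The multiple-kernel SVM

The inner problem is the standard soft-margin dual — maximize
`Σ αᵢ − ½ Σ αᵢαⱼyᵢyⱼ k(xᵢ,xⱼ)` under `Σ αᵢyᵢ = 0`, `0 ≤ αᵢ ≤ C` — solved
by sequential minimal optimization with maximal-violating-pair working
sets (compiled), to a KKT violation of `1e-8`. The bias averages
`yᵢ − f₀(xᵢ)` over margin support vectors, with a midpoint-of-bounds rule
when none exists.

The outer problem treats the dual optimum `J(β)` as a convex function of
the kernel weights on the probability simplex and minimizes it by reduced
gradient descent (the simpleMKL scheme): the gradient component for
network *m* is `−½ (αy)ᵀ K⁽ᵐ⁾ (αy)` at the current optimal `α`, the
direction is projected so that coordinates at zero cannot go negative,
and an Armijo backtracking line search from the full step to the simplex
boundary — warm-starting the SMO solver — chooses the step. Iterations
stop when the `β` change drops below `1e-4`, the objective change below
`1e-5`, or at 200 outer iterations (then the best iterate is returned
with a warning). The objective history is monotone non-increasing and the
suite checks the converged objective against an exhaustive `β`-grid +
interior-point-QP oracle.

Numerical conventions, all documented in the function help: each training
kernel is divided by its mean diagonal entry before mixing so that `β` is
comparable across networks of different scales (the same factor is
applied at test time); the RBF `gamma = "auto"` resolves to `1/d_m` per
network with `d_m` that network's selected-feature count; polynomial
kernels default to degree 3 with offset 1; `sign(0)` is `+1`; a network
with no selected features in a fold is dropped (`β = 0`) and the
remaining weights renormalized. For linear kernels the per-network
hyperplane `w⁽ᵐ⁾ = Σ αᵢyᵢxᵢ⁽ᵐ⁾` (including the normalization factor) is
exposed, and `Σ_m β_m ⟨w⁽ᵐ⁾, x⁽ᵐ⁾⟩ + b` reproduces the decision values to
machine precision.

## Evaluation without leakage

`loocv` holds out each subject once. Inside a fold, *in order*: scaling
statistics (mean/SD, `n−1`; zero SDs replaced by 1) are fitted on the
training rows only and applied to both sides; features are selected on
the training rows only; the model is trained; the single held-out subject
is scored. A regression test corrupts the held-out row and asserts the
fold's trained model is bit-identical — that is the leakage contract.

Three designs share this scaffold: `multi_kernel` (one kernel per
network, learned `β`), `single_kernel_fused` (all selected features
concatenated into one kernel — direct data fusion) and
`single_network:FN/FA/MD` (the selected set restricted to one block; when
the restriction is empty the block's top-ranked feature is used so the
baseline always trains). Accuracy, sensitivity and specificity come from
the pooled confusion counts with the patient group as positive class, and
the ROC/AUC from the pooled per-fold decision values via the rank
statistic with ties counted ½ — decision values, not calibrated
probabilities.

`grid_search` runs one full LOOCV per cell of
`C ∈ {0.5, 1, …, 5}` × `fraction ∈ {0.0014, 0.00145, …, 0.0028}` (10 × 29
cells by default) and reports the full surface; ties prefer fewer
features, then smaller C. The searched criterion is the reported
criterion — there is deliberately no outer nesting, so the best cell's
accuracy is an optimistically biased estimate; treat the surface as a
robustness display, not an unbiased error bound.

## Discriminative features

Only features selected in *every* fold are reported. Each consensus
feature's weight in a fold is `|w_j⁽ᵐ⁾| · β_m` — the absolute hyperplane
coefficient times that fold's weight of the feature's network — and the
report averages over folds, then sums per edge (across networks) and per
network. The three totals partition one grand total, which the suite
asserts. The report refuses nonlinear-kernel runs rather than
approximating input-space coefficients that do not exist.

## Problem sizes used by the test suite

The suite regenerates everything from code; the main experiments are a
90-node, 40 + 40-subject cohort with a 1.5-SD MD-only effect on 12 edges
(LOOCV accuracy, MD kernel-weight dominance and ≥ 80% injected-edge
recovery), a 200-replicate permutation null at 60 subjects on 30-node
networks (p = 1,305; chance-level mean accuracy), SMO-vs-QP and
MKL-vs-grid oracle comparisons at n ≤ 30, and Monte-Carlo calibration of
the generator at small n. The 30-node choice for the permutation null
keeps the null distribution estimate cheap; the null property does not
depend on the parcellation size.

## Known limitations

* Streamline input is the in-memory/JSON phantom format or NIfTI volumes
  plus voxel-index streamlines; binary TRK/TCK readers are not included.
* No multiclass extension (the intended use is binary group contrasts),
  no probability calibration, no alternative MKL formulations, and no
  k-fold/bootstrap defaults.
* The generator's shared topology and independent Gaussian edge noise are
  idealizations; conclusions about real MRI cohorts require real data.
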