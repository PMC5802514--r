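---
title: "Structural covariance network analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance network analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scovnet)
```

## The analysis in one paragraph

Chronic stress is hypothesized to reorganize the covariance structure of
regional brain anatomy: a global loss of network segregation (clustering,
modularity) together with a focal gain in the "hubness" of the amygdala.
`scovnet` implements the full analysis chain used to test this hypothesis in
a two-group design (rodent chronic-stress vs control, or high vs low
childhood trauma in humans): behavioral battery integration, per-region
volumetrics, group-level structural covariance networks thresholded across a
density grid, weighted graph metrics, group-label permutation inference with
AUC aggregation, and focal-node subconnectome characterization. A
latent-factor synthetic cohort generator supplies test substrates with
exactly the statistical structure the analysis assumes.

## Structural covariance networks

Structural covariance is a *group-level* construct: for each group
separately, the Pearson correlation of every pair of ROI volumes is computed
across that group's subjects. Negative correlations are discarded as
structural zeros (absent edges, not zero-weight edges). Because correlation
matrices of different groups are not directly comparable at a fixed
correlation cutoff, both matrices are thresholded to the same edge *density*
`d`: exactly `k = round(d * M)` strongest edges are kept (half-up rounding,
`M = n(n-1)/2`), and the analysis is repeated over a density grid — by
default 10% to 30% in 1% steps, the standard range in this literature. Ties
at the cutoff break deterministically by `(-weight, i, j)` lexicographic
order, which also makes edge sets nested along the grid.

Assumptions worth stating: subjects are exchangeable within group (no
longitudinal structure), volumes are approximately Gaussian after any
normalization, and covariance differences of interest express themselves in
the top-density tail of the correlation distribution.

## Weighted graph metrics

All metrics are computed on the thresholded weighted graph, implemented from
first principles (C++ kernels; no graph-library calls in the metric path)
and validated in the test suite against exhaustive brute-force enumeration
on all-pairs shortest paths for graphs of up to 7 nodes, and against igraph
as an independent cross-check:

* **transitivity** and **clustering coefficient** use the Onnela triple
  term `(w'_ij w'_ih w'_jh)^{1/3}` with weights normalized by the maximum
  retained weight; nodes of degree < 2 contribute zero clustering.
* **characteristic path length** is the mean shortest-path distance over
  connected ordered pairs with edge lengths `1/w`; disconnected pairs are
  excluded so the estimator is total at every density.
* **modularity** is the best Newman `Q` over repeated Louvain restarts on
  the weights (default 100 restarts for single-network estimates, 5 inside
  permutation loops — restart noise was measured to leave permutation power
  unchanged between 5 and 20). Restarts consume one deterministic RNG
  stream, so the best `Q` over the first `k` restarts is non-decreasing in
  `k` and runs are exactly reproducible.
* **nodal hubness**: degree (binarized), strength (summed weights),
  betweenness (Brandes accumulation on `1/w` distances, endpoints excluded,
  normalized by `(n-1)(n-2)/2`), and closeness in the reachable-scaled
  Wasserman–Faust form `((r-1)/Σd) · (r-1)/(n-1)`. Degree ranks share the
  minimum rank under ties, which is the conservative choice for hubness
  claims.

## Permutation inference

Group networks are functions of group membership, so the only exchangeable
unit is the subject's group label. `permute_metrics()` shuffles labels over
the pooled subjects (preserving group sizes), rebuilds both networks from
scratch at every density, and records stress-minus-control differences. One
permutation schedule is shared across all densities and metrics of a run:
this makes the per-density nulls and the trapezoid-AUC null mutually
coherent and lets the correlation matrices be computed once per
permutation. Empirical two-tailed p-values use the +1-corrected formula
`(#{|null| >= |obs|} + 1)/(n_perm + 1)`, which can never return zero and is
valid at finite `n_perm`. The study default is `n_perm = 10000`; the test
suite uses 200–1000.

A node is *flagged* when its p-value falls below `alpha` at
`min_consecutive` (default 2) or more consecutive densities — the a-priori
nodal criterion. The default subconnectome reporting density is the lowest
grid density at which any nodal difference is significant.

## The synthetic cohort generator

`generate_cohort()` draws volumes from a latent-factor model: every ROI
loads on a global factor (inter-module correlation `between_module_corr`),
its module's factor (raising within-module correlation to
`within_module_corr`), and idiosyncratic noise; all three stress
manipulations act on the loadings, so they are orthogonal, interpretable
knobs, and the implied covariance is PSD by construction (residual
variances are checked and generation errors rather than clips):

* `demodularization` multiplies within-module shared *variance* in the
  stress group;
* `hub_gain` adds one shared factor over `{hub_roi} ∪ hub_target_set` with
  loading `sqrt(hub_gain)`, raising those pairwise correlations by exactly
  `hub_gain`. A single shared factor is the only PSD-feasible way to raise
  ~30 hub correlations by 0.3 simultaneously; its side effect — the target
  set also gains mutual covariance, as a co-regulated subnetwork — is
  scientifically the intended reading of a shared-plasticity process;
* `volume_effect_size` shifts the mean of the affected ROIs by that many
  per-ROI SDs between groups, plus a 0.3-coefficient coupling to the
  group-centered latent emotionality trait. The pure trait-carried variant
  (shift = d·σ·trait/Δ) was rejected because it inflates within-group
  variance by `(d/Δ)²`, silently shrinking both the realized Cohen's d and
  every correlation involving the affected ROIs.

Behavioral variables load (coefficient 0.45) on a latent emotionality trait
whose group mean difference is `emotionality_effect_size`; variables flagged
`lower_is_more_emotional` load negatively, so direction metadata is
genuinely exercised. The loading makes a one-factor battery's first
principal component carry roughly a fifth of total variance at large n,
typical of rodent batteries. Volumes are plain Gaussians around baseline
means scaled to `mean/SD >= 12`, so volumes are positive without clipping
(generation errors if not). The volume, behavior, and latent-trait streams
are split deterministically from one master seed.

### Default study designs

`mouse_default_spec()`: 12 subjects per group, 155 ROIs in eight anatomical
modules, within/between module correlations 0.70/0.05, a 34-variable
battery over eight tests with a trait effect of d = 2, volume effects of
d = 1.5 on four prefrontal ROIs, and an amygdala hub (in the small
subcortical module) gaining 0.3 covariance with 30 targets spread over the
other modules under 0.7 demodularization. `human_default_spec()`: 237
low-trauma vs 299 high-trauma subjects, 56 ROIs in six modules, a weaker
focal gain (0.15) and attenuation (0.85), a single-ROI volume effect
(d = 0.4), and volumes on a mm³ scale with total-brain-volume and sex
covariates.

The free baseline parameters (module layout, correlation levels, target-set
placement) were calibrated once, by a power study at the rodent sample
size, before the test suite was frozen: the hub sits in a small module so
its covariance gain is not masked by a large within-module degree baseline,
its targets lie outside its own module, and the volume-emotionality
coupling is kept off the hub because variance added to the hub dilutes
exactly the correlations the hub effect is supposed to raise.

### What the generator does not emulate — and a detectability limit

The generator produces block-exchangeable Gaussian data. Real structural
covariance data have spatially smooth, heterogeneous correlations,
hemispheric symmetry, and heavy-tailed subject effects; none of these are
modeled, so passing tests show the *pipeline* behaves correctly under its
own assumptions, not that any particular biological dataset would yield the
same inferences.

One consequence deserves emphasis. With 12 subjects per group the sampling
noise of a Pearson correlation is roughly `SD(r) ≈ 0.3` — the same size as
the injected hub gain of 0.3. In a fixed top-k graph a node's retained-edge
count competes against the order statistics of ~10,000 noisy null
correlations, and under label permutation the injected effect itself leaks
into the null (mixed groups carry partial effects), widening it roughly in
proportion to the observed difference. Across a broad sweep of baseline
designs the nodal degree/strength permutation tests therefore stay near
their calibrated size at rodent scale, even for gains well above 0.3, while
the global modularity and transitivity reductions and the direction of the
hub's degree-rank shift are recovered in a majority of replicates. The
acceptance suite states the rodent-scale recovery targets at their full
strength and reports honest rates; `scripts/acceptance.R` recomputes these
rates at run time. At the human design's sample sizes (n ≈ 237/299) the
per-correlation noise is ~0.06 and the same machinery detects far subtler
effects.

## Volumetrics and behavior scoring

Per-ROI group comparisons use `lm(volume ~ group + covariates)` with
Benjamini–Hochberg control across ROIs; with no covariates the group
p-value equals the pooled-variance two-sample t-test exactly (asserted to
1e-10 in the tests). ROIs are ranked by `|t|`, a scale-free association
strength; a-priori-set enrichment among the top k uses the 2×2 chi-square
without continuity correction. The mouse preset analyzes absolute volumes
(with a separate total-brain-volume null test); the human preset divides by
total brain volume, adjusts for sex in the GLM, and residualizes on sex
before network construction — whether to residualize before correlation is
genuinely open, and the preset makes the choice explicit and overridable.

Emotionality z-scores are computed against the *control* group's mean and
SD, so the control mean is exactly zero and stress effects read in
control-SD units; variables pointing "down" are sign-flipped, z-scores are
averaged within then across tests. Behavioral PCA standardizes by pooled
mean/SD (the two groups are analyzed as one sample) and orients each
component so the stress-group mean score is not below the control mean,
making PC1 read as an emotionality axis. The number of retained components
is a parameter; the package takes no stance on a retention rule. Missing
values are rejected, not imputed.

## Numerical and interface choices

* `k = round(d·M)` with half-up rounding; rounding must be fixed for
  reproducibility, and half-up keeps `|k/M − d| ≤ 1/(2M)`.
* Near-equal shortest-path lengths (relative 1e-12) count as ties in
  betweenness accumulation; with continuous weights exact ties have measure
  zero.
* Every stochastic entry point takes an explicit integer seed, restores the
  caller's RNG state, and reruns byte-identically; derived sub-seeds stay
  below 2^31.
* Tables interchange as tidy CSV with JSON sidecars (ROI labels, variable
  metadata, generating spec); networks export as edge-list CSV and GraphML,
  including a two-graph subconnectome bundle whose edges are labeled
  `common`/`stress_only`/`control_only`.
* The 159-vs-155 ROI distinction (volumetric set vs network set with
  ventricles excluded) is handled by an explicit `roi_exclude` list rather
  than a hard-coded atlas.

## Problem sizes in the shipped checks

The test suite validates metric kernels on 200 random graphs of up to 7
nodes against exhaustive enumeration; calibrates the modularity permutation
test on 500 null cohorts (30 ROIs, 12 subjects/group, 200 permutations);
and runs the rodent-scale recovery study on 25 cohorts at full mouse
dimensions (155 ROIs, 1000 permutations, five densities). The acceptance
script repeats the calibration at 200 cohorts and the recovery study at 10
replicates of 500 permutations. These sizes were chosen so the whole suite
runs on a laptop in well under half an hour while keeping Monte-Carlo
standard errors small relative to the asserted bounds.
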