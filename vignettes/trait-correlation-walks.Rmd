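---
title: "Adaptive walks with evolving trait correlations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive walks with evolving trait correlations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitscape)
```

## The model

`traitscape` simulates phenotypic adaptation of a clonal microbial
population on an empirically anchored fitness landscape. The landscape (the
"trait-scape") is built from a multi-genotype trait table: K quantitative
traits measured on replicate cultures of each genotype under an ancestral
and an evolved (selection) condition. Traits are z-scored against the
evolved rows, a PCA is fitted to the standardized evolved matrix, and the
first `n_axes` (default 2) components define the landscape. A focal
genotype's ancestral centroid, projected onto the evolved axes, is the start
of the adaptive walk; its evolved centroid is the evolutionary endpoint.
Working on evolved axes means that trait combinations irrelevant to fitness
under the selection condition carry little weight in the fitness distance.

Each of the N individuals carries a K-vector of standardized trait values
*and* a K(K-1)/2-vector of heritable pairwise trait correlations (stored in
the canonical order 1v2, 1v3, ..., 3v4). Correlations are the individual's
"genetic architecture": they do not enter fitness directly, but they steer
how trait perturbations propagate, and they are inherited exactly under
selection. Per generation:

* a fraction `1 - p_corr` (default 90%) of individuals receives a **trait
  change**: one trait k is chosen uniformly, perturbed by a Gaussian step
  (sd `step_sd` = 0.05), and the remaining traits are updated through the
  individual's correlations (see *Propagation semantics* below);
* the remaining `p_corr` (default 10%) receive a **joint trait + correlation
  change**: one of the P pairs is chosen uniformly, its stored correlation
  perturbed by a Gaussian step and clipped to [-1, 1]; one endpoint trait of
  the pair is perturbed, and the other endpoint is rewritten from the new
  correlation and the new first-trait value. Other traits are untouched in
  that generation;
* fitness is evaluated as `w = exp(-z^2 / 2)`, z being the Euclidean
  distance between the individual's projected coordinates and the endpoint
  in retained-axis space, and the population is resampled with replacement
  proportionally to w (Wright-Fisher style, constant N).

Selection never sees the correlations; particular correlation structures
sweep only because of the trait dynamics they generate. Replicate walks
therefore converge on the same high-fitness region through *different*
correlation architectures — "cryptic phenotypes" — which the census and
clustering layers quantify.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `N` | 1000 | individuals | population size |
| `generations` | 2000 | generations | walk length |
| `replicates` | 100 | — | independent replicate walks |
| `p_corr` | 0.10 | fraction | share receiving the joint change (exact count `round(p_corr * N)` drawn without replacement) |
| `step_sd` | 0.05 | standardized trait units | sd of every Gaussian perturbation (traits and correlations) |
| `propagation` | `"replace"` | — | how trait changes propagate (below) |
| `mode` | `"mixed"` | — | standing-correlation initialization (below) |
| `n_axes` | 2 | axes | retained PCA axes; the fitness distance lives here |

Initialization modes: `mixed` draws every correlation iid Uniform(-1, 1) —
the no-bias null. `A1`–`A4` / `E1`–`E4` fix the m most significant
empirical ancestral / evolved correlations (by their significance rank in
the supplied correlation table) identically across individuals, leaving the
rest random — graded historical bias. `uncorrelated` zeroes all correlations
and disables propagation entirely; it is the control in which trait
dimensions evolve independently.

## Propagation semantics (a deliberately open choice)

The literal update rule for a trait change — "the other traits are updated
by multiplying the new focal-trait value by the stored correlations" — is
implemented as the default `replace` mode: `trait_j <- r_kj * trait_k`.
For standardized traits this is the conditional-expectation regression
update, but it is information-destroying: the previous value of `trait_j`
does not enter. Because the rule's source description is ambiguous, a
`delta` mode (`trait_j <- trait_j + r_kj * delta`) is provided behind the
`propagation` switch. All shipped defaults, tests and analyses use
`replace`. One observable consequence: with `step_sd = 0`, `delta` mode is
exactly state-preserving, while `replace` mode still rewrites non-focal
traits toward `r * trait_k`; the degenerate-step identity test therefore
runs in `delta` mode.

Correlation clipping keeps every stored value a valid correlation; the
implied K x K matrix is *not* forced positive semi-definite, because the
model treats the P pairwise correlations as independently evolving
quantities rather than as a consistent covariance structure.

## The phenotype census

A replicate's signature is the mean final-population correlation vector.
Signatures are clustered with UPGMA on Euclidean distance; k is chosen in
2..`k_max` by maximum mean silhouette width, declaring a single type when
the best silhouette is below 0.25 (a conventional "no structure" cut-off,
configurable). Accessibility of a type is the fraction of replicates in it.
The rate of adaptation is summarized as `1 / t95`, where t95 is the first
generation at which mean fitness reaches 95% of its plateau (the mean over
the final 10% of generations), guarded to 1 when a trajectory starts at the
criterion. This is a repo convention — the source framework colours rates
without defining them — so an area-under-curve alternative (`rate_auc`,
mean fitness as a fraction of the plateau) is reported alongside.

## Multiscale bootstrap AU p-values

Cluster support for the cross-mode meta-analysis is computed from scratch in
the pvclust tradition: the P feature dimensions entering the distance are
resampled with replacement at sizes `round(r * P)` for scales r in 0.5–1.4,
the UPGMA tree is rebuilt `nboot` times per scale, and each observed node's
per-scale appearance frequency is fitted to `BP_r = 1 - Phi(v sqrt(r) +
c / sqrt(r))` by binomial maximum likelihood (probit GLM), with a weighted
least-squares fallback on probit-transformed proportions (boundary counts
pulled in by 0.5/nboot) when the ML fit fails; the fallback is flagged in
the output. Then `AU = 1 - Phi(v - c)` and `BP_corrected = 1 - Phi(v + c)`.
Nodes present in all or none of the resamples short-circuit to AU = 1 or 0.
With P = 6 correlation dimensions the bootstrap is necessarily coarse —
resample sizes range over 3..8 — which is why `nboot` defaults to 1000 and
why AU values on small signature sets should be read qualitatively.
Convex hulls in correlation PC space are drawn for clusters with AU at or
above 0.75; the threshold direction follows the results-facing reading
("greater than 75") of the source convention.

## The synthetic reference fixture

`make_reference_fixture()` emulates the empirical design that motivates the
package — 4 traits, 5 genotypes, ancestral and evolved replicate cultures —
without reproducing any real measurement. Each (genotype, condition) cell is
a multivariate Gaussian; target correlation matrices are repaired to the
nearest PSD correlation (eigenvalue clipping plus unit-diagonal rescaling)
before sampling. Construction choices, made once:

* evolved genotype means lie mostly in a 2-D plane of trait space, so the
  evolved PCA concentrates >= 80% of variance on two axes (observed: ~95%);
* the focal genotype's ancestral centroid sits >= 2 retained-axis units from
  its evolved centroid, giving the walk a real distance to cover;
* within-cell trait sd is 0.4 raw units against a between-genotype spread of
  ~2 — replicate scatter clearly smaller than genotype differences, as in
  typical experimental-evolution trait data;
* the ranked significant ancestral correlations run from -0.89 (most
  significant) to 0.54 (least), matching the span reported for the
  motivating system, and are structurally misaligned with the evolved
  correlations (e.g. 2v4 strong ancestrally, uncorrelated evolved; 1v2 the
  reverse), so ancestral bias genuinely opposes the direction of selection.

What the generator does **not** emulate: measurement error models,
non-Gaussian trait distributions, unbalanced replication, batch effects.
A green simulation test on this fixture establishes that the engine
reproduces the qualitative phenomena (bias-dependent accessibility and
rate, cryptic-phenotype multiplicity, control convergence) in a world where
they are built in — not that any particular biological dataset behaves
this way.

## Numerical and statistical conventions

* **Standardization** uses the population-sd convention (divide by n),
  configurable to sample sd; PCA loadings carry a deterministic sign
  (largest-magnitude entry positive) for bit-reproducibility.
* **RNG**: replicate r consumes a private stream seeded `base_seed + r`;
  within a generation the draw order is fixed (corr-subset indices; pair
  indices; correlation deltas; endpoint choices; trait deltas of the joint
  group; focal indices and deltas of the trait group; resampling).
* **Smoothed-fitness monotonicity** is asserted statistically: the
  replicate-ensemble mean trajectory, averaged over 50-generation windows,
  may not drop by more than 0.02. Individual replicates show real transient
  dips (median ~0.04, up to ~0.15 after smoothing) as correlation
  architectures reorganize near the plateau; a per-replicate zero-tolerance
  reading of "non-decreasing" is not true of this model and is not asserted.
* **"No new phenotypes"** under alternative starts is operationalized as:
  a variant type is *new* only if its mean-correlation vector is farther
  from every baseline type than baseline types are from each other
  (fallback radius 1.0 in the [-1,1]^6 correlation space when the baseline
  has one type).
* **Configuration files** are flat JSON (no YAML dependency); unknown keys
  are rejected rather than ignored.

## Known limitations

* Mean population fitness at the mutation–selection–drift balance scales
  with N (drift load): on the reference fixture the plateau runs ~0.45 at
  N = 100 to ~0.73 at N = 1000. *Adaptive outcomes* (which phenotypes
  emerge, that walks reach the high-fitness region) are robust across these
  sizes, but a "final mean fitness within 0.1 across N" reading of
  population-size robustness does not hold at desk scale and is documented
  rather than asserted.
* With P = 6 dimensions the multiscale bootstrap's scale grid collapses to
  a handful of distinct resample sizes; (v, c) estimates on real signature
  sets are correspondingly noisy (the parameter-recovery tests use
  simulated counts at nboot = 10^4).
* The walk is purely phenotypic: no loci, linkage, explicit mutations,
  overlapping generations or environmental fluctuation, and no coupling to
  an ecosystem ODE layer.
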