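---
title: "Individual morphological brain networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual morphological brain networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Structural covariance networks describe how regional brain morphology
covaries *across* people, so they exist only at the group level. Individual
(single-subject) morphological networks instead treat each atlas region's
distribution of voxel-level gray-matter volume (GMV) as a probability
distribution, and define the connection strength between two regions of the
*same* subject as the similarity of those two distributions. The result is
one network per person, which can be carried into ordinary case-control
statistics: graph-topology summaries per subject, then group tests on those
summaries.

`morphnet` implements this construction end to end for a 90-region AAL
parcellation, together with a synthetic cohort generator that emulates a
two-group clinical morphometry study, so that every stage — density
estimation, divergence-based similarity, sparsity-swept graph topology, and
the group-level statistical battery — is testable without access to raw
MRI.

## From voxels to networks

**Regional distributions.** For one subject, the voxel values of each
region are turned into a discrete probability mass function by Gaussian
kernel density estimation with Silverman's rule-of-thumb bandwidth
(`stats::bw.nrd0`), evaluated on a grid shared by all of the subject's
regions, multiplied by the grid spacing and renormalised to sum to one.
The shared grid spans the subject's pooled value range padded by three
times the largest regional bandwidth, so every pairwise comparison has
common support and all kernel mass is effectively on-grid. Discretising
*then* normalising means all divergences are between finite discrete
distributions — bounded, symmetric where expected, and free of quadrature
error terms. The default resolution is 256 points (tests and simulations
use 128 where the extra resolution is irrelevant); a refinement study in
the test suite shows successive grid doublings change the resulting
distributions by a JSD that shrinks monotonically toward zero.

**Similarity edges.** Two similarity measures are implemented:

* `JSDs = 1 − JSD(P, Q)` with base-2 logarithms, where
  `JSD = H(M) − (H(P) + H(Q))/2`, `M = (P + Q)/2`, and `H` is Shannon
  entropy with the `0·log 0 = 0` convention. Base-2 JSD is bounded in
  `[0, 1]`, so the similarity is too: identical distributions score 1,
  disjoint supports score 0. The metric variant `1 − √JSD` is available as
  a switch (`transform = "one_minus_sqrt_jsd"`); the linear form is the
  default because it is the construction used by the individual-network
  method literature this package follows.
* `KLDs = exp(−(KL(P‖Q) + KL(Q‖P)))` with natural logarithms, after both
  distributions are floored at `1e-12` and renormalised (KL is undefined
  on zeros of the reference distribution; flooring is deterministic and
  bounded). `KLDs` lies in `(0, 1]` and equals 1 exactly when the floored
  distributions coincide.

The 90×90 matrix of pairwise similarities, with a forced zero diagonal, is
the subject's network. Self-similarity is excluded because self-loops are
not edges in the thresholded graphs.

**Sparsity sweep and AUC.** A sparsity `S` keeps the
`K = round(S·N(N−1)/2)` largest-weight edges as an unweighted graph (ties
broken by ascending lexicographic node pair, so results are deterministic
across platforms, and edge sets are nested across `S`). Metrics are
computed at every threshold from 0.05 to 0.40 in steps of 0.01 (36
thresholds) and summarised by the trapezoidal area under the curve, which
is exact for curves linear in `S`. Binarised rather than weighted graphs
are used because the sparsity definition is an edge-count ratio and the
reference tooling for this analysis family operates on binarised networks.

**Graph metrics.** Global: mean local clustering coefficient `Cp` (nodes
of degree < 2 contribute 0), characteristic path length `Lp` (mean
shortest-path length over reachable pairs; disconnected graphs are
averaged over within-component pairs and flagged rather than returning
infinities), global efficiency `Eg` (mean inverse distance, 0 for
unreachable pairs), local efficiency `Eloc` (mean over nodes of the global
efficiency of each node's neighbour-induced subgraph), and the small-world
indices `γ = Cp/⟨Cp_null⟩`, `λ = Lp/⟨Lp_null⟩`, `σ = γ/λ`, normalised
against degree-preserving (Maslov–Sneppen) rewired null networks. Nodal:
nodal efficiency `Ne`, degree centrality `DC`, nodal local efficiency
`NLe`, and unnormalised betweenness centrality `BC` (group contrasts are
scale-invariant, so no normalisation is applied).

The metric kernels are compiled (Rcpp): BFS distances, bitset triangle
counting, Brandes betweenness, and frontier-expansion BFS for
neighbour-subgraph efficiency. Note that `NLe` here is the efficiency of
the subgraph *induced by the neighbours* — paths may not leave the
neighbourhood — which differs from implementations that only delete the
index vertex. The test suite pins every kernel against hand-written
brute-force oracles (Floyd–Warshall, explicit triangle counts, exhaustive
geodesic enumeration) on all 208 non-isomorphic graphs with up to six
nodes, and against igraph where definitions coincide.

**Null models.** The null count defaults to `n_null = 100` with `10·|E|`
swap attempts per network, the convention of the reference tooling; both
are configurable since the source analyses rarely state them.
`subject_curves(n_null = 0)` skips `γ/λ/σ` entirely — the raw and
efficiency metrics do not need null networks — which is what the
simulation suites use when normalised metrics are not part of the measured
outcome. If a degenerate null family (zero mean clustering) makes `γ`
undefined, the package warns and reports `NA` rather than a number.

## Group statistics

* Demographics-style panels: Shapiro–Wilk at α = 0.05 per group gates
  between a pooled-variance Student t-test and a Mann–Whitney test
  reported as a tie-corrected normal-approximation `Z` (no continuity
  correction) — the two statistic types found in clinical summary tables.
  The pooled (not Welch) t is also what reproduces the published summary
  statistics this package's acceptance checks recompute.
* Categorical variables: Pearson chi-square without continuity correction,
  df = 1.
* Network AUCs: a linear model of the AUC on an intercept, group
  indicator, and covariates (age, sex, education, TIV by default); the
  group coefficient's t is the reported statistic. With no covariates this
  is exactly the pooled two-sample t. Rank-deficient designs are an
  explicit error naming the collinear columns.
* Nodal metrics: the group model is fitted per region, then
  Benjamini–Hochberg FDR is applied across the 90 regions *within each
  metric's family* (the conservative reading when pooling is unstated;
  a single pooled family can be obtained by passing one metric at a
  time).
* Brain-behaviour associations: partial Pearson correlations — residuals
  of both variables after regression on the covariates — with
  `t = r√((n−2−k)/(1−r²))`.
* `HOMA-IR = FINS × FBG / 22.5` is provided as a vectorised helper and is
  the definition used by the cohort generator.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline's statistical behaviour is demonstrated.

Each cohort has fixed "anatomy": per-region mixture locations
(`U(0.45, 0.65)`), voxel-level spreads (`U(0.06, 0.12)`), two-component
separations and weights, and voxel counts (`U[200, 2000]` by default,
spanning small to large AAL regions). Subjects get regional mean shifts
driven by shared latent factors (5 by default) plus independent noise, so
regions with similar factor loadings remain mutually similar within every
subject — the source of reproducible network structure. Voxel values are
two-component Gaussian mixtures truncated at zero, giving smooth
unimodal-to-bimodal regional densities like real GMV histograms.

The patient group receives, in the designated effect regions (defaults:
anterior cingulate, hippocampus, parahippocampal gyrus — AAL indices 31,
32, 37, 38, 39, 40), a downward mean shift of `effect_size` regional
spreads (default 1.0) and a `variance_effect`-fold spread inflation
(default 1.5). Both changes make the affected regions' distributions less
similar to the rest of the cortex, so their top-K edges drop out: their
nodal metrics shift, and the global clustering and local-efficiency AUCs
decrease on average in the patient group. The spread inflation is the
stronger lever for the global effect — during design, a 1.25-fold
inflation moved nodal metrics reliably but left the global clustering
difference near zero, while 1.5 produces the consistent reduction the
generator is meant to emulate; 1.5 is also a scientifically reasonable
description of atrophy increasing within-region heterogeneity. The
regional-mean bulk is kept about two voxel-spreads wide so that a shift of
one regional spread moves a region an appreciable fraction of the bulk —
with a much wider bulk, the same standardised shift often relocates a
region into an equally dense similarity neighbourhood and produces no
network-level signature at all, which would make the generator's injected
effects unrecoverable by construction rather than by statistics. Even so,
the designated-region effect is probabilistic at the network level: for
some anatomy draws a region's shifted distribution still resembles its
neighbours, which is why recovery rates are quoted per seed rather than
guaranteed.

Clinical panels are drawn from distributions matched to the moments and
quantile scales of a typical diabetes case-control table (log-normal for
skewed chemistry panels parameterised by median and IQR on the log scale,
truncated normal for age in 35–70, Bernoulli sex ratios 88/150 vs 70/130,
integer cognitive scores clipped to their instrument ranges), and the
insulin-resistance index is computed from the generated insulin and
glucose by the formula above — emulation targets realistic scales, not
replication of any particular data set.

**What the generator does not emulate:** scanner physics, spatial
smoothing, registration error, spatial autocorrelation between neighbouring
regions, site effects, or realistic inter-regional correlation of effect
sizes. Passing tests therefore demonstrate the pipeline's statistical
machinery is correct and calibrated under a plausible generative model —
not that any particular clinical finding would replicate.

## Numerical choices and degenerate inputs

* Strict mode (default) refuses zero-variance regional samples and
  all-identical subject values; permissive mode substitutes a nominal
  bandwidth `max(1e-6, 1e-6·|mean|)` (widened to one grid spacing if that
  is below the grid's resolution) and warns on every fallback.
* Similarities are clamped to their theoretical ranges to absorb
  floating-point jitter at the boundaries (e.g. JSD a few `1e-16` above 1).
* Top-K tie-breaks, null-model seeds, and the per-subject seed offsets in
  cohort sweeps are all deterministic; identical configuration and seed
  give byte-identical outputs, which the pipeline test verifies.
* Disconnected thresholded graphs never produce `NaN`/`Inf` in any
  returned metric; `Lp` carries a disconnection flag instead.

## Problem sizes used by the test and acceptance suites

The simulation suites run at deliberately reduced problem sizes chosen to
make their statistical targets measurable while keeping the full suite
quick on a laptop: null-calibration uses 400 cohorts of 15+15 subjects
with 6 regions; FDR calibration uses 150 null AUC tables of 20+20 subjects
with 90 regions; effect recovery runs the full construction on 12 cohorts
of 40+40 subjects (and 10 of 30+30 for the global-effect direction) with
90 regions, 120–300 voxels per region, and a 128-point grid. These sizes
are the package's own choices and are stated here so they can be scaled up
by anyone wanting tighter Monte-Carlo error.

## Known limitations

* Voxel/vertex-wise inference (cluster-level family-wise error, surface
  reconstruction) is out of scope; the region-level covariate-adjusted
  linear model is the inference unit.
* Only unweighted graphs are analysed; weighted-graph metrics, rich-club,
  modularity and hub classification are not implemented.
* Kernel density estimation is fixed-bandwidth Gaussian without boundary
  correction; GMV values near zero can leak mass below zero before
  renormalisation.
* The exact similarity transform used by any given published analysis
  (`1 − JSD` vs `1 − √JSD`; the KLD exponent's constant) is often
  unstated; both JSD forms are provided and switchable, and agreement
  between JSD- and KLD-based results is itself checked in the tests (rank
  correlation of edge weights, concordant group statistics).
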