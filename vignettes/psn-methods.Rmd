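---
title: "Patient similarity networks: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient similarity networks: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psntools)
```

## The model

A patient similarity network represents each participant as a node and
connects participants whose multivariate clinical profiles are similar. The
pipeline in `psntools` is built for cohorts described by a moderate number
of continuous features — in the motivating application, 36 brain volumes
(subcortical structures, cerebellum, corpus callosum segments, cerebral
white matter and cortex, normalized to intracranial volume) and 6 RBANS
cognitive indices over 78 participants (49 IBS patients, 29 healthy
controls). The analysis asks three questions: do participants form
communities of similar brain–cognition profiles; do those communities align
with the diagnostic labels; and which features drive network position.

The pipeline is: mean imputation → z-scoring → pairwise distances →
Gaussian-kernel similarities → kNN + threshold sparsification → Louvain
community detection → agreement statistics and resampling inference →
centralities, feature importance, community profiling, and sensitivity
sweeps.

## Preprocessing choices

**Imputation.** Missing feature cells are replaced by the observed column
mean. This is defensible only because missingness is assumed sparse (the
emulated cohort has two missing cells out of 78 × 36 morphometric entries);
the package makes no attempt at model-based imputation.

**Standardization.** Features are z-scored with the *population* SD
(divide by n). The choice of denominator is immaterial downstream — the
kernel bandwidth is data-adaptive, so a global rescaling of the feature
matrix leaves the graph unchanged (this invariance is tested) — but it must
be fixed for reproducibility, so it is fixed and documented here. RBANS
indices are already age-normed to a population mean of 100 (SD 15); they
are z-scored anyway, since the purpose of the transform is to put all
features on a common scale *within the sample*, not to re-norm them.

**IBS-SSS is metadata, not a feature.** Symptom severity is deliberately
excluded from network construction and reserved as an independent clinical
validator; including it would trivially separate patients from controls and
make the agreement analysis circular.

**The composite cognitive score.** The RBANS Total Scale index is a
composite of the five domain indices. `drop_total_scale()` (or
`exclude_total_scale = TRUE` in `run_psn_analysis()`) runs the 41-feature
variant to check that results are not driven by this redundancy.

## Network construction parameters

| Parameter | Default | Meaning |
|---|---|---|
| `metric` | euclidean | distance between standardized feature vectors (cosine and correlation available) |
| bandwidth σ | mean pairwise distance | Gaussian kernel scale `s = exp(−d²/2σ²)` |
| `k` | 8 | nearest neighbours per node (≈ 10% of n = 78) |
| `threshold` | 0.3 | minimum retained kernel similarity |

The bandwidth is computed over the n(n−1)/2 *unordered distinct* pairs
(diagonal excluded); including the zero diagonal would shrink σ and is the
less standard reading of "all pairs". σ is recomputed per metric, per
cohort, and inside every bootstrap replicate.

Sparsification uses **union** symmetrization: {i, j} is a candidate edge if
either endpoint ranks the other among its k most similar neighbours. Union
(not mutual-intersection) semantics is the choice consistent with average
degrees above k, as observed in the motivating study (12.03 at k = 8).
Ties in the ranking are broken toward the lower participant index, making
construction deterministic. A node may therefore have degree above k, and
isolated nodes stay in the node set.

## Community detection

Louvain modularity maximization is implemented in the package (igraph's
implementation is used in tests only, as a cross-check). The two phases —
greedy single-node moves in seeded-random sweep order, then aggregation of
communities into a weighted supergraph — repeat until no move improves Q.
Numerical policies, all chosen because the method itself does not prescribe
them and determinism is required:

- moves are accepted only if the modularity gain exceeds `tol = 1e-7`;
- ties in the best target community go to the lowest community label;
- the sweep order is reshuffled each pass from the partition seed;
- the greedy search is restarted `n_restarts = 4` times from consecutive
  sub-seeds and the highest-Q partition kept (ties to the earliest
  restart). A single greedy run lands in a visibly suboptimal local
  optimum on a few percent of small random graphs; four restarts push the
  exhaustively verified optimality rate on ≤ 7-node graphs above 95% while
  keeping the result a pure function of `(graph, seed)`;
- final labels are contiguous integers ordered by decreasing community
  size.

Modularity is optimized on the *weighted* adjacency (kernel similarities)
by default, since the modularity definition used takes `A_ij` to be the
edge weight; binary modularity is available via `weighted = FALSE`, and
degree/density summaries are always unweighted. Whether the original
analysis weighted its Louvain run is not documented; the weighted default
is this package's choice.

## Agreement statistics and inference

**ARI** uses the chance-corrected pair-counting form on the contingency
table. Degenerate tables (both partitions trivial) return 0 with a warning.

**NMI** normalizes mutual information by the **arithmetic mean** of the two
marginal entropies. This convention is pinned by the published
community × diagnosis table: of the four standard normalizations (min,
geometric, arithmetic, max), only the arithmetic mean reproduces the
published value of 0.037 from the published counts. Entropies are in nats;
the normalization makes the result base-invariant.

**Permutation test.** Diagnosis labels are permuted with the network held
fixed. The decision p-value uses the add-one convention
`(1 + #{replicate ≥ observed}) / (B + 1)`, which is valid under
exchangeability and can never reach 0; the plain exceedance proportion is
reported alongside. Ties count toward exceedance (conservative).

**Bootstrap.** Each replicate resamples participants with replacement and
reruns the *entire* pipeline — standardization, distances, bandwidth,
kernel, sparsification, Louvain — on the resampled table, comparing the
replicate's communities to the *resampled* diagnosis labels. Duplicated
participants are retained as distinct nodes (their distance is 0 and kernel
similarity 1). Replicates whose graph has no edges are skipped and counted;
more than 10% skips is an error. CIs are the 2.5th/97.5th percentiles
(type-7 quantiles).

**Modularity null.** Community labels are permuted over nodes (sizes
preserved) and Q recomputed, yielding a z-score and an add-one empirical
p-value. If the null replicates have zero spread the z-score is undefined
and the function raises an error carrying the replicate values.

## Centralities and feature importance

Degree centrality is `degree/(n−1)` on unweighted edges. Betweenness uses
unweighted (hop-count) shortest paths — the analysis does not define an
edge-length transform for weighted paths, so the unweighted choice is
adopted and documented. Eigenvector centrality is the L2-normalized leading
eigenvector of the *weighted* adjacency, by power iteration (tolerance
1e-10, max 1000 iterations); on a disconnected graph it is computed on the
largest component with other entries zero-filled and a warning.

Feature importance is the Spearman correlation of each standardized feature
with degree centrality; p-values use the t-approximation with average-rank
ties, and Benjamini–Hochberg FDR adjustment spans all features in the
active run (42, or 41 without the composite score). Exact rank-test
enumeration is used only in tests at tiny n.

## Community profiling

Profiles report counts and original-scale mean ± SD of age, IBS-SSS and
RBANS Total per community. IBS-SSS is summarized over IBS members only —
controls carry no severity score, and imputing one would be meaningless.
SDs of size-1 communities are reported as absent, not 0. The
Kruskal–Wallis effect size is `η² = (H − k + 1)/(n − k)`; small-H values
can drive this formula below 0, in which case it is clamped to 0 with a
warning. The chi-square test on the community × diagnosis table uses no
continuity correction (df > 1). Distinguishing features rank all features
by within-community mean z-score, reporting the three most elevated and
three most reduced.

## The synthetic cohort generator

`generate_cohort()` draws each planted subgroup's feature rows from a
multivariate normal with mean `δ · s_g` — `s_g` an independent random ±1
sign vector per subgroup, loosely echoing the mixed elevated/reduced
profiles such cohorts show — and equicorrelated covariance (unit variances,
correlation `ρ_w`). Diagnosis is Bernoulli per subgroup; age and RBANS
Total are normal; IBS-SSS is normal truncated to [0, 500] *by resampling*
(clipping would pile mass at the bounds) and stored only for IBS
participants. The RBANS Total used for profiling is generated as a separate
metadata column on its natural scale, while the 42 network features stay on
the latent z-like scale; this keeps the null configuration (δ = 0, ρ_w = 0)
exactly i.i.d. standard normal, which the tests rely on.

`ibs_cohort_spec()` fixes the study-shaped conditions: subgroup sizes
23/12/23/20; IBS probabilities 15/23, 9/12, 10/23, 15/20 (expected IBS
count 49 of 78); per-subgroup age, severity and cognition (mean, sd) pairs
taken from the published community profiles; and two missing morphometric
cells in distinct participants. Treating those published per-community
summaries as *generative* parameters is an explicit emulation assumption —
they describe detected communities, not ground truth. Defaults `δ = 3`,
`ρ_w = 0.2` give clearly separated subgroups: the regime in which community
recovery can be validated (ARI vs planted > 0.9) while diagnosis agreement
stays at chance, mirroring the central finding that communities cut across
the diagnostic labels.

What the generator does *not* emulate: the real cohort's feature
covariance (anatomically neighbouring volumes are strongly correlated in
real data), measurement noise structure, or item-level cognitive scores.
Passing tests therefore establish correctness of the pipeline's
computations and calibration of its inference under a known model — not
that real brain-morphometry cohorts contain four subgroups.

One consequence of strong planted separation deserves note: at δ ≥ 3 with
k = 8 (below every subgroup size), each node's nearest neighbours are all
within its own subgroup, so the kNN graph has one dense component per
subgroup rather than a single connected component. The connectedness
observed in the real network is a weak-structure phenomenon; the robustness
tests accordingly check both regimes (component count unchanged under 45%
edge removal for the separated graph; a single maintained component for the
δ = 0 graph).

## Sensitivity analyses

- **Metric comparison** reruns the pipeline per distance metric at fixed
  (k, threshold).
- **Parameter grid** covers k ∈ {5, 8, 10, 15} × threshold ∈ {0.2, 0.3,
  0.4, 0.5} (16 conditions); edge counts are monotone along both axes,
  which the tests assert.
- **Edge removal** deletes ⌊f·E⌋ uniformly chosen edges for f = 0, 0.05,
  …, 0.45, reruns Louvain, and records agreement and component counts. The
  grid stops at 45% — the fraction range actually reported in the
  motivating results — with `R = 10` repeats per fraction by default (a
  single trajectory is the R = 1 special case).

## Problem sizes used in validation

The test suite and the end-to-end checks run at the study's own scale
(n = 78, 42 features) with replicate counts reduced to keep the suite
fast: bootstrap checks use 40–200 replicates (the analysis default is
1000), permutation calibration uses B = 199 across 100 simulated null
cohorts, and exhaustive-search cross-checks of Louvain use graphs of up to
7 nodes, where all partitions can be enumerated.

## Known limitations

- Mean imputation and the equicorrelation model are deliberately simple;
  neither is appropriate for cohorts with substantial missingness or
  strongly structured covariance.
- Louvain is greedy; even with restarts it offers no optimality guarantee,
  and alternative partitions of near-equal modularity may exist (no Leiden
  refinement or multi-resolution scan is provided).
- The bootstrap compares replicate communities to the *resampled* labels;
  comparing to original-cohort labels is a different estimand and is not
  implemented.
- Betweenness ignores edge weights by design; a `1 − s` length transform
  would be a reasonable alternative and can be emulated through igraph on
  the exported graph.
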