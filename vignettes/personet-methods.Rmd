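---
title: "Methods: multi-omic network integration for personality transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic network integration for personality transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(personet)
```

`personet` links variably transcribed genes to personality-associated
genomic networks through shared brain regions, builds minimum interaction
networks around the resulting gene subsets, and characterizes the
regulatory network anchored on the hub the networks share. This vignette
is the package's own account of the models, the synthetic-data design,
the numerical choices, and their limitations.

## 1. Expression preprocessing and group statistics

Input is a subjects × genes matrix of log2 intensities with one
personality-profile label per subject. `quantile_normalize()` forces every
subject's distribution onto the across-subject mean quantile profile (ties
averaged; delegated to limma's implementation). Gene selection ranks by
pooled variance across all subjects; `method = "between_profile"` instead
ranks by variance of the per-profile means, for analysts who read "most
variable across profiles" as a between-group statement. Ties break by
ascending identifier so the selection is total and reproducible.

`profile_anova()` is classical one-way ANOVA with Tukey HSD pairwise
follow-up; pairwise effect sizes are point-biserial Pearson correlations
(magnitudes near 0.2/0.5/0.8 read as small/medium/large). A zero
within-group variance input is flagged degenerate (`F = Inf`, `p = 0`)
rather than erroring, since planted fixtures can legitimately produce it.

`bootstrap_profile_anova()` resamples subjects with replacement within
each profile, averages each gene within each profile, removes the
per-gene grand mean, and runs a one-way ANOVA with the centered gene-level
means as observations and profiles as groups. The centering matters:
per-gene baselines vary by orders of magnitude more than any profile
contrast, and without it the between-gene variance swamps the
between-profile signal regardless of effect size. The unit of analysis
(genes as observations after within-profile averaging) is one defensible
reading of a bootstrap over network-averaged expression; it is exposed as
configuration rather than buried.

## 2. Fuzzy NMF biclustering

The factorization is standard Frobenius NMF, `X ≈ WH` with nonnegative
factors and multiplicative updates; the objective trace is recorded and is
non-increasing per step (asserted in the tests). "Fuzzy" enters at
extraction: loadings are row-normalized into memberships summing to 1 over
the `k` factors, and a bicluster keeps the subjects and genes whose
membership reaches the threshold (default `1/k`, the uniform-spread
exceedance rule). Members can belong to several biclusters, which is the
point of the fuzzy reading.

Numerical choices:

* **Nonnegativity transform.** The default subtracts each gene's minimum
  (`shift = "gene_min"`) rather than the single global minimum. The
  per-gene baseline is almost exactly a rank-1 component of the data, and
  with a global shift it competes with the planted block structure for
  factors: on synthetic data with block effect equal to twice the noise
  standard deviation, gene-assignment adjusted Rand index versus the
  planted blocks is ~0.5–0.8 under a global shift and 1.0 under the
  per-gene shift (10 seeds). The applied offset is recorded in the fit;
  `"global_min"` and `"none"` remain available.
* **Initialization and determinism.** Uniform random `W`, `H` given a
  seed; a fixed seed reproduces the factors bit for bit. `n_runs > 1`
  keeps the run with the lowest final reconstruction error, a lightweight
  stand-in for consensus schemes; the default is a single, fully
  auditable run.
* **Stopping.** Relative objective change below `tol` (default `1e-6`) or
  `max_iter` sweeps.

Model-order selection is out of scope; `k` is fixed by the caller (7 in
the replication profile).

## 3. Brain-region colocalization

For a gene set, `region_scores()` averages the set's rows of a
genes × regions atlas. `region_significance()` tests over-expression
one region at a time against a null of equally sized gene sets drawn from
the atlas without replacement: `p = (1 + #{null mean ≥ observed}) /
(1 + n_perm)`, corrected across regions (Bonferroni by default, BH
available). The test is one-sided because only over-expression is
biologically read here. Under the null the p-values are uniform (a
Kolmogorov–Smirnov check at 200 replicates is part of the test suite).
The permutation scheme is this package's stand-in for the external
colocalization service the design emulates, whose internals are not
published; it is the natural exchangeable-genes null for the statistic.

A transcriptomic bicluster and a genomic-environmental gene set whose
significant regions intersect form a GET subset; the gene payload is the
union with provenance, and the two sets need not share genes — indirect
(region-mediated) association is the mechanism of interest.

With Bonferroni across `R` regions at level `alpha`, the smallest
attainable adjusted p is `R / (1 + n_perm)`; `n_perm` must be chosen
accordingly (the pipeline default 1999 with `alpha = 0.05` over ≤ 20
regions leaves headroom; the acceptance script uses 4999 at
`alpha = 0.01`).

## 4. Networks, minimization, hub

Networks are built first-order: seeds plus every node adjacent to a seed
on the requested layers, with all edges among the collected nodes. Edge
direction (TF→gene, miRNA→gene) is metadata; connectivity is undirected
throughout, because the minimum network is a connectivity construct.

`minimum_network()` removes non-seed nodes greedily — candidates in
ascending degree, ties by ascending betweenness then identifier — keeping
a removal only if the number of seed-bearing connected components is
unchanged, and repeating to a fixed point. The result retains all seeds
and a *minimal* connector set: no proper subset of the retained connectors
preserves seed connectivity. On every ≤ 12-node instance in the test
suite this is verified against exhaustive enumeration of all connector
subsets. The greedy order is this package's determinism rule; a different
rule could return a different (equally minimal) set when several exist.

`merge_networks()` takes node/edge unions (seed role wins; conflicting
biotype annotations are an error), `shared_hub()` intersects two node
sets and partitions by biotype, and `connect_gets()` reports the
connectors that remain after minimizing the network built on the union of
GET gene sets.

## 5. Hub expansion and modules

`expand_hub()` collects all direct interactors of the hub on the
miRNA-gene and protein–protein layers and keeps hub-incident edges only,
giving a hub-centric network: gene–gene edges among interactors are
deliberately excluded by default because the expansion queries hub
interactions, and the modular structure of interest is anchored on the
hub. Each interactor records its regulator signature — the exact subset
of hub miRNAs targeting it.

Module labels are canonical: M1–M3 are the two-miRNA signatures in
descending member count, M4 the all-three signature, M5–M7 the single-miRNA
signatures in descending member count, and M8–M10 the miRNA clusters of
the hub proteins in hub order. A miRNA touching several hub proteins is
assigned to each such module and flagged, rather than forced unique — the
single-assignment rule would be arbitrary. Genes with neither a hub-miRNA
edge nor a hub-protein miRNA-cluster membership (e.g. protein partners of
hub proteins) are reported as unassigned rather than erroring.

Node metrics: degree; local clustering coefficient
(triangles over wedges, isolates 0); eigenvector centrality by power
iteration on `A + I`, normalized to maximum 1, computed on the largest
component (others 0, flagged). The unit diagonal shift is required
because the hub-centric network is bipartite-like and plain power
iteration on `A` oscillates; the shift preserves eigenvectors. The dense
`eigen()` decomposition serves as an independent oracle in the tests
(agreement to 1e-6 on 50-node graphs). Communities come from igraph's
multi-level (Louvain) modularity maximization under a fixed seed, with
the partition's Q reported.

`extend_with_lncrna()` adds, for every interaction involving a
personality-associated lncRNA, the non-lncRNA partner to the network. The
lncRNAs themselves are tracked as linkers and not counted among the
network genes, matching how the extension's gene count is reported
(regulated genes only).

## 6. Enrichment statistics

`set_enrichment()` computes the 2×2 Pearson chi-square without continuity
correction plus the two-sided Fisher exact test. The reported fractions
are annotation rates inside the member set versus in the whole background
universe (member count / member total against annotation count /
universe size), which is how such comparisons are conventionally printed;
the chi-square itself uses the proper disjoint 2×2 cells. The background
defaults to the full genome-scale universe supplied by the caller rather
than the expression-array universe — both are valid conditioning choices
and the caller picks by passing the universe. Percentages are reported
raw and at the roundings used in prose (integer, one decimal).

## 7. The synthetic-data module

The generators are pure functions of a configuration and a root seed;
each draws from a substream keyed by stage name (`substream_seed()`), so
adding a stage never perturbs another stage's draws.

What is emulated, and the chosen study conditions:

* **Expression** (`gen_expression()`): per-gene Gaussian baselines
  (mean 7, sd 0.8 on the log2 scale — typical normalized microarray
  intensities), i.i.d. noise (sd 0.5), disjoint planted gene blocks
  elevated by 2 log2 units in overlapping subject subsets (25–45% of
  subjects), and an ordered per-profile shift (creative 1.0 >
  organized 0.5 > unregulated 0.0) on a responsive gene subset. The
  replication profile has 459 subjects (125/241/93) and 34,602 genes with
  7 blocks of 104 genes. Expression is generated directly on the
  post-normalization scale; probe-level noise, backgrounds and batch
  effects are not modeled, so passing tests say nothing about raw-array
  artifacts.
* **Atlas** (`gen_atlas()`): gamma-distributed nonnegative expression
  (shape 4, mean 5) with an additive boost of 3 for enriched (set,
  region) pairs. The boost is a power choice: the smallest planted gene
  sets must clear the beat-all-permutations threshold that Bonferroni at
  small alpha implies, with margin against the right-skewed null maxima
  of gamma means. Four bicluster/GE-set pairs share 9 distinct regions in
  the fixture design.
* **Interactions** (`gen_interactions()`): a hub star realizing all 7
  regulator signatures with configurable counts (replication counts give
  3919 protein-coding genes, 198 miRNAs, 38 pseudogenes, 35 other ncRNAs
  = 4190 interactors), plus two seed chains whose first-order networks
  prune to exactly 45 and 43 nodes sharing the 6 hub genes. Chain nodes
  adjacent to a hub gene are drawn from that hub gene's own interactor
  pool so the expansion counts are not perturbed; decoy leaves give the
  pruning real work. Two lncRNA tables are emitted: an expansion table
  whose partners extend the network to 4376 genes, and a link table of
  102 edges from 20 lncRNAs onto existing members. The printed extension
  arithmetic cannot be realized by a single table (102 edges cannot
  introduce 186 new genes), so the two reported quantities come from the
  two tables through the same function.
* **Annotations** (`gen_annotations()` / fixture planting): Bernoulli
  LLPS membership at the background rate (0.157 high-throughput) in the
  generic generator; the replication fixtures instead plant exact
  per-pool counts so that the enrichment worked examples land on fixed
  numbers (1699 of 4376 members; 9571 and 72 of the 61,035-gene
  universe; module rates 59.0/57.5/52.2/62.5%). The planted M3 rate is
  52.2% — the nearest value attainable with a 67-gene module.

Determinism, truth round-tripping, and destruction of the profile effect
under label permutation are asserted in the test suite. The fixtures are
statistical emulations: identifiers are synthetic (`G000001…`,
`mir-A/B/C`, `HUBP1…`), and no claim is made that planted structures
behave like any real interactome beyond the properties stated above.

## 8. Pipeline, problem sizes, provenance

`run_pipeline()` chains the stages over a fixture bundle with one root
seed and returns a report carrying every stage artifact plus a provenance
block (seed, parameter set, configuration hash, package version). Seed
gene sets for the network stage are taken from the bundle's designated
seed lists when present — in replication use the seed lists are inputs —
otherwise from the GET payloads.

Problem sizes used by the shipped checks are deliberately modest and are
the package's own choices: unit tests run on tens-of-subjects bundles;
the bicluster-recovery property uses 60 × 140 matrices over 10 seeds; the
acceptance script generates the full 459 × 34,602 replication expression
matrix, runs the factorization on a 400-gene subsample (the bicluster
count, not the factor content, is the reported quantity there), and uses
4999 permutations per colocalization test.

## 9. Known limitations

* The greedy minimum network returns one minimal connector set; global
  minimum-cardinality Steiner-style optimization is not attempted.
* The colocalization null treats genes as exchangeable within the atlas;
  correlated atlas rows (co-expression blocks) would make it liberal.
* The fuzzy membership threshold `1/k` shares many genes among biclusters
  on diffuse data; analyses needing sharper sets should raise it.
* The bootstrap ANOVA's gene-as-observation design ignores gene-gene
  correlation, so its F is calibrated only relative to its own null
  (which the tests check empirically).
* Community detection on the hub-centric star reflects the hub-anchored
  topology; retaining the full induced interactor subgraph would change
  the partition and is intentionally not the default.
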