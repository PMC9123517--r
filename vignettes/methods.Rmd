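---
title: "Methods: inverse-signature drug repurposing and IMC phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverse-signature drug repurposing and IMC phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvrsig)
```

`pvrsig` packages the computational arc of a fibrotic-membrane
transcriptomics study — disease signature, interaction-filtered target
list, catalog-filtered drug candidates, inverse-signature connectivity
ranking, cell-type enrichment, and single-cell IMC phenotyping — as
composable, seeded, testable functions. This vignette records the models,
the parameters that matter, and the numerical conventions, so that every
choice a user might need to question is written down.

## Disease signature

### Differential expression stand-in

`internal_de()` is deliberately a light-weight two-group procedure, not a
negative-binomial GLM:

* library sizes are normalized by **median-of-ratios size factors**
  (reference = per-gene geometric mean over samples; genes with a zero
  anywhere are excluded from the reference, with a library-size fallback);
* the effect estimate is `log2fc = log2((mean_dis + 0.5) / (mean_ctl + 0.5))`
  on normalized counts. The **pseudocount 0.5** avoids infinite fold
  changes at zero means and is the common default in count-based effect
  reporting;
* the p-value is a **Welch unequal-variance t-test** on
  `log2(normalized + 1)`, vectorized over genes; BH adjustment across all
  tested genes.

Genes with zero counts in every sample are reported (`log2fc = 0`,
`p = 1`) but flagged `tested = FALSE` and excluded from multiple testing —
"expressed" means a nonzero count in at least one sample. A location test
on log counts is adequate for building a ranking and for planted-effect
recovery on synthetic data; it does not model dispersion shrinkage, and no
equivalence with NB-GLM tools is claimed. Analyses that need a shrunken
estimator can inject any external DE table through `read_de_csv()` —
ranking by the raw `log2fc` column is the default behaviour either way.

### Thresholds and ranking

`filter_degs()` uses **strict** inequalities — log2FC > 2 (or < −2) *and*
BH-adjusted p < 0.05 — so boundary values are excluded; both cutoffs are
arguments. `rank_signature()` orders by log2FC descending with
**lexicographic tie-breaks** on the gene id: file order never influences
the ranking, which keeps every downstream permutation test reproducible
across input shufflings.

### ORA and BH

`ora_hypergeometric()` is the standard upper-tail hypergeometric
over-representation test with a user-supplied flat annotation set and
universe (no ontology-graph handling). `bh_adjust()` exposes step-up BH
(delegating to `stats::p.adjust`); both are pinned by exhaustive-
enumeration oracles in the test suite.

## Interaction retention

`filter_by_interaction()` counts degree **within the subgraph induced on
the signature genes**: the screen asks which disease genes form an
interacting core, not whether a gene has any partner anywhere in the
proteome. The score threshold for keeping an edge defaults to 400,
STRING's "medium confidence", and is configurable; identifiers are
matched as exact strings (symbol/Ensembl mapping is the caller's
responsibility).

## Connectivity scoring

### The statistic

For a ranked signature of $N$ genes with scores $s_1 \ge \dots \ge s_N$
and a drug down-set $S$ ($n = |S \cap \text{ranking}|$), the running sum
gains $|s_i|^p / \sum_{j \in S} |s_j|^p$ at members and loses
$1/(N - n)$ at non-members; the enrichment score is the signed extremum of
maximal absolute deviation. Conventions:

* **weight exponent** $p = 1$ by default (classic weighted GSEA); $p = 0$
  reduces the statistic exactly to the two-sample Kolmogorov–Smirnov
  distance between hit and miss rank distributions (property-tested);
* if every member score is zero at $p = 1$ the hit weights fall back to
  uniform rather than dividing by zero;
* on an exact tie between the positive and negative extremum the positive
  one is reported;
* the leading edge contains members at or before a positive extremum (at
  or after a negative one).

The implementation evaluates the extremum from hit positions alone in
$O(n)$, which is what makes permutation calibration cheap; a full
running-sum vector is available on request for enrichment-curve plots.
Equality with a position-by-position brute-force walk (tolerance
$10^{-12}$) and with an independent GSEA implementation (`fgsea`) is
enforced in the tests.

### Calibration

The null is **gene permutation**: enrichment scores of uniformly random
gene sets of the same size drawn from the ranking. With a single fixed
disease ranking, phenotype permutation is simply not available, and random
gene sets are the standard pre-ranked GSEA null. Conventions:

* one-sided p with the +1 correction,
  $p = (1 + \#\{|ES_0| \ge |ES|,\ \text{same sign}\}) / (1 + \#\{ES_0\ \text{same sign}\})$,
  so $p \ge 1/(n_{perm}+1)$ and a permutation test can never report zero;
* **sign-split NES**: $ES / \mathrm{mean}(|ES_0|\ \text{of matching sign})$,
  which keeps NES comparable across set sizes and asymmetric nulls;
* `score_drugs()` shares one null per distinct intersection size across a
  drug batch — identical results to per-drug nulls from the same seed,
  at a fraction of the cost;
* defaults: `n_perm = 1000`, seed always required. With 21 candidates and
  BH correction, 1000 permutations put the smallest achievable adjusted p
  comfortably below 0.05; fewer permutations quantize p too coarsely to
  survive correction.

Only the *downregulated* drug gene set is scored: the screen's question is
whether the genes a drug suppresses sit atop the disease ranking.
`rank_drugs()` applies BH across all scorable drugs and orders by NES
descending, ties by adjusted p then name.

## Cell-type enrichment

`ssgsea_score()` implements the single-sample enrichment integral: genes
ranked by expression (descending, lexicographic ties), score
$\sum_i [P_{hit}(i) - P_{miss}(i)]$ with rank-position weights
$(N - i + 1)^\alpha$ normalized over members, $\alpha = 0.25$ by the usual
ssGSEA convention. The statistic depends only on ranks — invariant under
any monotone transform of expression — and no cross-sample rescaling is
applied, so each score is a pure function of one sample. The reference
cell-type method this stands in for additionally aggregates multiple
signatures per cell type, calibrates scores against a compendium and
compensates spillover; none of that is reproduced here (its signature
database is proprietary), so absolute score magnitudes are not comparable
with published cell-type scores — only within-analysis contrasts are
meaningful. Group comparison (`compare_groups`) is an exact-enumeration
Mann–Whitney U (exact for both groups ≤ 8, even under ties; tie-corrected
normal approximation beyond), BH-adjusted across cell types.

## IMC phenotyping

* **Normalization**: each marker divided by its 99th percentile across
  cells, clipped to [0, 1] — robust to the heavy right tail of mean pixel
  intensities. All-zero markers stay zero with a warning.
* **Clustering**: k-nearest-neighbour sets (Euclidean, self included,
  distance ties broken by a seeded shuffle of cell indices), **Jaccard
  overlap between every pair of neighbourhoods** kept as an edge when it
  reaches 1/15, Louvain modularity at resolution 1. We use the
  shared-nearest-neighbour formulation (as in the Seurat and scran
  clustering stacks) rather than reweighting only the kNN edges: scoring
  all neighbourhood pairs makes a homogeneous population a near-complete
  subgraph, and modularity then recovers well-separated populations
  whole, whereas the kNN-edge-only graph retains enough geometric
  substructure that modularity shatters single populations into spurious
  sub-communities at the same resolution. Defaults `k = 15`,
  `resolution = 1`; cluster ids are relabelled 1..K by decreasing size.
  An arcsinh pre-transform is deliberately *not* applied before
  clustering; percentile normalization already brings markers to a common
  scale.
* **Profiles**: per-cluster marker means plus z-scores standardized per
  marker *across cluster means* (z = 0 where the across-cluster sd is 0),
  matching the usual cluster-heatmap convention.
* **Composition**: counts per (cluster, entity), mean counts per sample
  within entity, and an attribution rule — a cluster belongs to an entity
  when ≥ 80% of its cells carry that label, else "shared". Published
  cluster-to-entity assignments rarely state their criterion; 0.80 is an
  explicit, configurable stand-in.
* **Gating**: positivity is `normalized intensity > threshold` with
  threshold 0.5 on the [0, 1] scale by default. Published co-expression
  percentages almost never state the positivity rule, so the threshold is
  a required, logged parameter rather than a hidden constant; boolean
  AND/OR combinations of co-markers are supported. Positive and negative
  percentages partition to 100 by construction.

## Synthetic data: what it emulates, and what it does not

The generators define the conditions under which the pipeline is
validated:

* `simulate_bulk_counts()`: negative binomial with
  $Var = \mu + \alpha\mu^2$, baseline means log-uniform on $[1, 10^4]$
  (the common dynamic range in RNA-seq simulation), shared dispersion
  $\alpha = 0.1$ in the standard scenario, planted effects as exact
  mean multipliers $2^{\text{lfc}}$. Transcript lengths are drawn
  log-uniform on [300, 10⁴] bp for TPM exercises.
* `simulate_drug_catalog()`: one planted drug whose down-set overlaps the
  top-$n$ window of the signature (defaults: 30 of the top 50), decoys
  with uniformly random down-sets, attributes arranged so the planted
  drug always passes the catalog filter (filter behaviour is tested by
  dedicated failing decoys); every drug gets 3 targets inside the top
  window so target mapping does not silently thin the screen.
* `simulate_network()`: Erdős–Rényi edges among non-orphans; orphans have
  degree 0 by construction and must never survive interaction filtering.
* `simulate_cell_matrix()`: Gaussian noise around population marker means,
  truncated at zero. The standard clustering scene uses an 18-marker
  panel — the size of a realistic IMC antibody panel — with two
  populations; in very low-dimensional scenes (2–3 markers) the
  nearest-neighbour graph of even a single Gaussian population carries
  genuine geometric substructure, and community detection legitimately
  subdivides it, so low-dimensional scenes are used only for gating
  tests, where they are exact.

None of the generators model batch effects, gene–gene correlation,
read-level error, spatial structure of images, or inter-sample
heterogeneity of cell populations. Passing the planted-recovery tests
therefore demonstrates that the pipeline's machinery is correct and
calibrated — not that the method will rank the right drug on real tissue,
where signature quality, catalog coverage and perturbation-reference
fidelity dominate.

## Problem sizes and determinism

The validation suite runs at deliberately desk-friendly sizes: 2000 genes
× 16 samples for the end-to-end screen (100 replicates), 1000 random
instances for the enrichment-score oracle, 500 runs × 1000 permutations
for calibration, 200 cells × 18 markers for clustering. Every stochastic
function takes an explicit seed and restores the caller's RNG state;
repeated runs — including the CLI subcommands — are bit-identical, which
the suite checks byte-for-byte on the written CSVs.

## Known limitations

* The DE stand-in underuses count dispersion information; very small
  groups (n = 2–3) will have noisy rankings.
* NES magnitudes depend on the sign-split normalization convention;
  comparing NES across tools with different conventions is not
  meaningful.
* The exact Mann–Whitney branch enumerates $\binom{n_1+n_2}{n_1}$
  assignments and is restricted to groups ≤ 8.
* Cell-type scores are relative quantities; no deconvolution to
  proportions is attempted.
* Graph clustering recovers what the neighbourhood graph can see: rare
  populations below ~k cells and populations separated only in markers
  dominated by noise will not be resolved.
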