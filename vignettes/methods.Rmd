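---
title: "Methods: seed-gene-centered cross-species network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-gene-centered cross-species network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccnnet)
```

## The problem

The CCN family (CCN1–CCN6) are matricellular proteins that sit at the
interface of growth factor signaling, extracellular matrix assembly and
mechanotransduction during chondrogenesis. Rather than studying their
expression in isolation, this package characterizes their *regulatory
neighborhood*: the set of genes that are co-expressed with CCN members
during differentiation **and** interact with them at the protein level,
compared across species (human, mouse, chicken) and resolved at the
single-cell level. The pipeline has six computational stages, each of
which is exercised end-to-end on a synthetic study with known ground
truth.

## Co-expression modules

The co-expression stage follows the weighted-network paradigm with a
**signed hybrid** adjacency: for genes $i, j$ with Pearson correlation
$r_{ij}$ across samples,

$$a_{ij} = \begin{cases} r_{ij}^{\beta} & r_{ij} > 0 \\ 0 & r_{ij} \le 0\end{cases}$$

so anti-correlated genes never share a module. Pearson correlation is
used (not a robust midcorrelation) because it admits exact analytic
oracles in tests. Zero-variance genes are dropped before correlation,
since their correlation is undefined.

The soft power $\beta$ can be chosen by the scale-free topology
criterion (`pick_soft_power()`): connectivities $k_i = \sum_j a_{ij} - 1$
are binned (at least 5 occupied bins) and the $R^2$ of
$\log_{10} f(k) \sim \log_{10} k$ is evaluated per candidate power
(default candidates 1–20, target $R^2 \ge 0.8$, fallback 9 when no
candidate qualifies — the conventional fallback for signed-hybrid
networks on small sample sizes). Small simulated designs rarely produce
convincing scale-free topology, so the bundled analyses run at a fixed
$\beta = 6$ and report the fit table alongside.

Gene–gene similarity for clustering is the **topological overlap**

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},$$

which rewards shared neighbors over direct adjacency alone. One
consequence worth noting: the textbook claim "identical rows with
$a_{ij}=1$ give $\mathrm{TOM}=1$" holds only for binary adjacencies;
for weighted rows the formula gives less than 1, and the tests assert
the formula, not the folklore.

Modules are detected by average-linkage hierarchical clustering on
$1 - \mathrm{TOM}$ with a **static height cut** at a fixed fraction
(default 0.98) of the maximum merge height, and clusters below
`min_module_size` (default 30) are relabeled `grey` (unassigned). A
static cut was chosen over the dynamic hybrid cut because it is fully
deterministic and testable against planted partitions; the dynamic cut
is an explicit non-goal. Surviving modules are named in decreasing size
order with the conventional module color sequence, so the largest
module is always `turquoise` — mirroring the convention in which the
dominant, seed-containing module carries that name. When detected
modules tie in size, color order follows cluster index, so a test should
assert "turquoise is *a* largest module", not "the unique largest".

Each module is summarized by its **eigengene**: the first right singular
vector of the per-gene z-scored module submatrix, sign-oriented to
correlate nonnegatively with the module's mean profile (this makes
results independent of gene-row order). Module–trait association is the
Pearson correlation of the eigengene with culture day, with a two-sided
p-value from the $t$ distribution on $n-2$ degrees of freedom; tests
validate this against a permutation oracle. Seed modules are the
non-grey modules that contain at least one seed gene and are
trait-significant at $\alpha = 0.05$.

## Seed-centered PPI networks

Protein interactions are consumed as STRING-style exports
(`protein1`, `protein2`, `combined_score`). The score dialect
(0–1000 vs already-normalized 0–1) is auto-detected (any value > 1
implies the 0–1000 scale), and the confidence threshold (default 0.4,
medium confidence) is applied **inclusively** — the source convention
states the threshold but not inclusivity, so the inclusive reading is
declared here. Duplicate pairs keep the maximum score; self-loops are
dropped.

For each seed-containing module, the PPI graph is restricted to the
module's genes and the **first neighbors** (proximal proteins) of the
seed genes are extracted: the node set is the seeds plus every direct
interactor, and *all* induced edges among those nodes are kept (not
just the seed star), since neighbor–neighbor edges are part of the
published network topology. Seeds absent from the PPI file are retained
as isolated flagged nodes — a species lacking an annotated seed
ortholog (as chicken lacks CCN6) must not abort the run. Module-level
networks are merged by node/edge union with per-node provenance, and
hubs are ranked by unweighted degree on the merged graph (degree on the
merged graph is a declared choice; per-module degrees remain available
by running `first_neighbors()` per module), ties broken
alphabetically, default top 15.

## Stability under resampling

Two resampling summaries quantify robustness:

* **Subsample bootstrap** (default 10 iterations at 80% of samples,
  drawn *without replacement* — "80% of samples" reads as subsampling,
  and the report records the scheme): the full-data partition is the
  reference, and each rerun is compared by a **best-match,
  size-weighted Jaccard**: for each non-grey reference module the best
  Jaccard overlap with any rerun module is taken, then averaged with
  size weights. Grey genes are excluded so unassigned genes cannot
  dominate the unions. The published per-species indices do not define
  their matching scheme, so this declared metric is recorded in every
  report; exact numeric agreement with externally published indices is
  therefore not expected.
* **Single leave-out** (default 10% of samples removed once): the whole
  module + network pipeline is rerun and the retention rate is the
  fraction of reference seed-network genes still present.

A pure-noise input typically yields an all-grey reference partition, in
which case the Jaccard metric raises its declared undefined-metric
error; analyses treat that as the degenerate zero-stability outcome,
since no module reproduces at all.

## Ortholog conservation

Ortholog tables (`gene_a`, `gene_b`, `homology_type`) are filtered to
**strict one-to-one pairs**: a pair survives only if its A-side symbol
occurs exactly once among all A entries and its B-side symbol exactly
once among B entries, the tabular equivalent of unique reciprocal
best hits. Symbols are compared case-insensitively after whitespace
stripping (mouse `Ccn1` vs human `CCN1`), preserving display case in
reports.

For a functional category with gene sets $A$ and $B$ in the two
species, with $S$ the one-to-one-mapped shared pairs:

* species-A-centered index $= |S| / (|S| + |A\text{-only}|)$,
* species-B-centered index $= |S| / (|S| + |B\text{-only}|)$,
* Jaccard $= |S| / (|S| + |A\text{-only}| + |B\text{-only}|)$,

and the Jaccard never exceeds either centered index (a tested
invariant). Whether "category genes" means enrichment-term genes or
network genes annotated to a term is left to the caller; the bundled
pipeline intersects term genes with each species' seed network
(translating the B side through the ortholog map). Three-way overlaps
translate all species into species-A symbol space, check the pairwise
maps for mutual consistency (inconsistent genes are excluded with a
message) and fill the standard 7-region Venn diagram. The homologous
network intersects two seed networks on one-to-one nodes and takes the
**union** of edges (recorded per edge), since the published procedure
intersects gene content, not interactions.

## Enrichment

Over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ with population $N$ (the universe), $K$ term genes and $n$
query genes, with Benjamini–Hochberg control across tested terms; terms
with zero overlap are omitted. The universe defaults to all genes in
the species' expression matrix — the standard expressed-background
choice; the full genome is equally valid and configurable. Significant
terms roll up into five principal functional categories (ECM/structural,
cell fate & development, cytoskeleton, microenvironmental response,
signaling networks) via ordered keyword rules (first match wins,
unmatched terms are `unclassified`); the shipped rule list
(`inst/extdata/category_rules.tsv`) is a starting point and is
user-editable, since no canonical term-to-category assignment is
published.

## Single-cell stage

QC removes cells by detected-gene bounds and mitochondrial fraction and
then genes detected in too few cells, **cells before genes**, with
boundary rules read literally: "more than 5%" removes only strictly
greater values, "fewer than 200" keeps exactly 200. Two pre-registered
profiles exist: the hiPSC profile (200, 7000, 5%, genes in $\ge 3$
cells) and the embryonic-limb profile (200, 6000, 10%, no gene
filter). Normalization scales each cell to the median total count and
applies $\log(1+x)$ — a deliberately minimal stand-in for heavier
variance-stabilizing pipelines, which are out of scope. Clustering,
embedding and batch integration are *inputs* (cell annotations come
with the data), not computations.

Per-cell gene-set activity uses a **recovery-curve AUC**: genes are
ranked per cell by decreasing expression (ties broken lexicographically
— a strict total order is required for a cumulative curve and makes
scores platform-independent), and with $T = \lceil \text{top\_frac}
\cdot n \rceil$ the score is $\sum_{t=1}^{T} h(t)$ (cumulative set hits
in the top $t$) divided by its maximum achievable value
$\sum_{t=1}^{T}\min(t, m)$, so the best case is exactly 1 and the
worst 0. The default `top_frac` of 5% follows the cited convention and
is configurable since the original analyses do not state it. A
**rank-sum** alternative (Mann–Whitney-U-based, ranks clipped at
`max_rank`, default 1500) is provided as the UCell-style second
opinion. Ligand–receptor strength is a declared simplification of
probabilistic ligand-activity frameworks: mean ligand expression in a
sender population times mean receptor expression in a receiver
population, which preserves the ranking of strongly co-expressed pairs
without their prior networks.

Trajectory summaries include per-gene percent-of-reference-day tables
(genes with reference mean at machine zero are flagged and excluded
rather than divided by) and sample PCA (genes centered, unit-scaled
when variance is positive; component signs fixed by the first gene's
loading).

## What the synthetic study emulates — and what it does not

`generate_bulk_multispecies()` builds per-species time courses (default
4 days × 3 replicates) in which planted modules share low-order
orthogonal-polynomial latent profiles of culture day — module 1 gets
the monotone (linear) profile, mimicking maturation, and hosts the
designated CCN-like seed genes; other modules get higher-order
profiles, and background genes are pure noise. `generate_ppi()` makes
edges denser within planted modules; `generate_orthologs_and_genesets()`
mixes one-to-one, one-to-many and species-specific genes (seed and
designated core genes forced one-to-one so a planted conserved core
exists); `generate_singlecell()` draws negative-binomial counts (fixed
dispersion 2) with one population's planted gene set shifted up on the
log scale, a planted ligand/receptor pair elevated in sender/receiver
populations, mitochondrially tagged genes, and one deliberate violator
of each QC rule. Every generator is a pure function of its parameters
and seed.

The simulations do **not** emulate sequencing error, batch effects,
library-size confounding between populations, dropout structure beyond
the negative binomial, or realistic gene-set overlap structure. Passing
tests therefore demonstrate correctness of the computations and
recoverability of planted structure under the stated noise model — not
performance on real accession data.

## Problem sizes and numerical choices

The bundled analyses and tests use the standard fixture — 3 species,
3 modules × 30 genes, 12 samples, `noise_sd` 0.3 (with a 90-gene,
background-free variant where exact recovery is the point), ~400 cells
× 300 genes for the single-cell stage — sizes at which every stage
completes in seconds while leaving headroom for the planted structure
to be non-trivial. Module recovery is summarized by the adjusted Rand
index against planted labels; at `noise_sd = 0` recovery is exact
(ARI = 1), and at 0.3 it stays at or above 0.9. Other choices:
correlations at exactly 0 are excluded by the signed-hybrid rule
(`> 0`); TOM values are clipped to [0, 1] and symmetrized against
floating-point drift; eigengene sign ties (zero correlation with the
mean profile) keep the SVD's sign; degree ties in hub tables break
alphabetically; the undefined cases (no non-grey reference module, both
category sets empty, empty query after universe filtering) raise
informative errors rather than returning silent zeros.

## Known limitations

* The static tree cut can absorb a few background genes into large
  modules at high cut heights; with background-free fixtures recovery
  is exact.
* The stability Jaccard is one of several defensible matching schemes;
  comparisons across implementations must match definitions first.
* The enrichment stage is a flat over-representation test: no ontology
  graph propagation, no ranked statistics.
* The ligand–receptor score is a mean-product heuristic; it ranks
  planted signals correctly but is not a probabilistic inference.
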