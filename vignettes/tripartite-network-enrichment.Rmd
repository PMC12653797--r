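---
title: "Tripartite network analysis and multi-method enrichment: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tripartite network analysis and multi-method enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytonet)
```

phytonet analyzes plant–compound–gene relationship tables as typed tripartite
networks and scores the targeted genes against gene-set collections with three
complementary enrichment methods. This vignette is the package's account of
the underlying models, the parameters that matter, the numerical choices made
where definitions leave room, and what the bundled synthetic fixtures do and
do not establish about real data.

## The data model and its assumptions

The input is a relationship table: one row per observed relationship, with a
mandatory `gene` column and optional `compound` and `plant` columns. The
package assumes relationships are symmetric associations (a compound "targets"
a gene, a plant "contains" a compound) with no direction, sign, or affinity;
edge weights, when requested, count supporting rows, nothing more. Ingestion
is split deliberately into a non-mutating validation pass and a separate
cleaning pass so both can be audited: validation records every rule violation
with its row and field, cleaning normalizes whitespace, uppercases gene
symbols, strips compound-name characters outside `A–Za–z0–9 _()+'-` (a set
chosen to preserve common phytochemical punctuation such as
`(+)-catechin` while removing formatting noise), drops rows with an empty
gene, and removes exact post-cleaning duplicates. Length windows (genes 2–50,
compounds 3–100, plants 1–150 characters), the 100 MiB size warning, the 50%
invalid-row warning and the 1000-rows-per-entity cap are data-quality
heuristics, not biological claims; all are adjustable via
`validation_rules()`.

Two representation choices deserve a note. Missing optional values become
`NA`, never the empty string, so "the table has no plant layer" and "this row
has a blank plant" stay distinguishable in the statistics. And duplicates are
defined as exact (gene, compound, plant) triples after cleaning — the simplest
reproducible definition; near-duplicates (synonyms, salts of the same
compound) are out of scope.

## The tripartite network

`build_network()` creates one node per distinct entity and an edge per
distinct co-occurring pair, restricted to the gene–compound and
compound–plant layers. Gene–plant edges never exist; this is a structural
commitment, asserted on every build and before every serialization. Orphan
genes stay in the graph as isolated nodes, because their share is itself a
data-quality signal.

One consequence is worth stating plainly: a layered tripartite graph contains
no triangles (any triangle would need a forbidden gene–plant edge), so the
average clustering coefficient of a valid network is exactly 0. The metric is
still computed — it becomes informative the moment a user loads a graph with
additional intra-layer edges — but for in-type networks the community
structure, not clustering, carries the signal.

Centrality conventions, where the literature offers several:

* degree centrality is `degree/(n−1)`;
* betweenness is unnormalized (a star center on 4 leaves scores 6, the number
  of leaf pairs);
* closeness uses the reachable-fraction convention
  `(r/D)·(r/(n−1))` for a node reaching `r` others at total distance `D`,
  which is bounded in [0, 1] on disconnected graphs and gives isolated nodes
  0;
* eigenvector centrality is computed on the largest connected component by a
  deterministic shifted power iteration — iterating `(A + I)x` has the same
  leading eigenvector as `A` but cannot oscillate on bipartite structures,
  and every layered tripartite graph *is* bipartite (compounds versus the
  rest). Tolerance 1e-6, at most 1000 iterations, failure is an error naming
  the component; nodes outside the largest component score 0. The
  deterministic start vector also makes centrality tables byte-reproducible
  across runs, which an ARPACK random start does not guarantee.

Hub compounds are counted by distinct gene targets (not total degree, which
would let plant attachments inflate a compound's apparent polypharmacology);
the default threshold of 5 targets marks the conventional multi-target
boundary and is configurable. When a partition is supplied,
`topology_summary()` also reports the R² of a least-squares fit of log
community size against log rank — a descriptive statistic of heavy-tailedness,
chosen because the size-versus-rank regression is the simplest reproducible
reading of "sizes follow a power law"; it is reported, not tested.

## Communities and the configuration-model null

Louvain (multilevel modularity optimization, resolution default 1) provides
partitions; the attached quality score is always the Newman–Girvan modularity
at resolution 1, `Q = Σ_c [e_c/m − (d_c/2m)²]`, recomputable from the
assignment and the graph. Tie-breaking is fixed by the seed, and community
labels are canonicalized by earliest member, so identical inputs give
identical partitions.

Significance comes from a configuration-model ensemble realized by double-edge
swaps rather than stub matching: stub matching creates self-loops and
parallel edges that would have to be erased (distorting the degree sequence)
or kept (violating simplicity). Swaps are additionally constrained *within*
each layer — a gene–compound edge only ever swaps with another gene–compound
edge — so every replicate preserves each node's exact degree, its type, and
the layer structure. This is a stricter null than an unconstrained
configuration model: it asks "is the community structure stronger than
expected among graphs that are still valid tripartite networks?", which is
the biologically meaningful comparison here, and it is the documented choice
wherever the stricter null could make the ensemble less variable than an
unconstrained one. Each replicate attempts `10 × |E|` swaps per layer, a
standard mixing allowance; a layer with fewer than two edges is left
unchanged with a warning.

The empirical p-value is (+1)-corrected, `p = (1 + #{extreme}) / (1 + B)`,
upper-tailed by default for modularity and clustering (a two-sided option
exists), so it can never be 0 and is floored at `1/(B+1)`. Convergence is
monitored at checkpoints 100, 200, …, B: at checkpoint `t` the coefficient of
variation is the standard deviation of the cumulative means recorded at
checkpoints in `(t/2, t]` divided by the cumulative mean at `t` (a window
with fewer than two checkpoints reports 0). On the default synthetic network
the CV stays well below 0.02 from checkpoint 500 onward and the cumulative
mean at 1000 sits within 0.5% of its half-way value, which is the package's
evidence that 1000 replicates suffice at this scale.

## Enrichment engines

**ORA.** Upper-tail hypergeometric `P(X ≥ k)` via `phyper`, with the
multiple-testing family restricted to sets that pass the size filter
(in-background size ≥ 3 by default): filtering after testing would
misstate the family size. Benjamini–Hochberg is the default correction;
Bonferroni is available for conservative reporting. The exact tail cannot be
0, but values are floored at the smallest positive double as a guard.

**Preranked GSEA.** The ranking for relationship tables is the gene's number
of distinct targeting compounds (its degree into the compound layer), ties
broken lexicographically — the natural "how strongly is this gene implicated"
score when no expression data exist; a preranked file is accepted in its
place. Phenotype permutation is impossible without samples, so the null is
gene-tag permutation: `n_perm` random same-size member sets, the documented
deviation risk being that gene–gene correlation structure is not preserved.
ES is the signed maximum deviation of the weighted running sum (hit weight
`|score|^w`, `w = 1` by default; an all-zero-weight set degenerates to the
unweighted statistic). NES divides ES by the mean magnitude of same-sign null
ES values; the raw p is the (+1)-corrected same-sign tail, hence floored at
`1/(n_perm+1)` — the zero-p rule; FDR follows the pooled signed null-NES
procedure, positive and negative sides separately. The minimum overlap is 3
in this mode, matching ORA, so the two engines test comparable families.
Implementation note: the walk's extrema can only occur at hit positions or
immediately before them, so ES is computed from the hit positions alone in
`O(|S| log |S|)` — this is an exact reformulation, tested against a
step-by-step walk oracle and an external reference implementation.

**GSVA.** Requires an explicit gene × sample expression matrix with at least
3 samples (a relationship table has no sample dimension, so the pipeline
skips GSVA with a logged reason when no matrix is supplied). Per gene, a
Gaussian-kernel cumulative density across samples with bandwidth `sd/4`;
per sample, ranks symmetrized as `|p/2 − r|^τ` (τ = 1); per set, a signed
running sum over genes in decreasing density order, scored as maximum
positive plus minimum negative deviation, bounded in [−1, 1]. The `sd/4`
bandwidth and the symmetric rank weighting follow the method's original
published form. A zero-variance gene has no usable bandwidth and is assigned
the flat density 0.5 everywhere — it then carries the middle rank and near-zero
weight, which is the least-informative, least-surprising fallback. Because
the bandwidth is proportional to each gene's own standard deviation, scores
are exactly invariant to positive affine transforms of any gene's values —
a property the test suite asserts, along with agreement to 1e-10 with an
independently coded direct-formula oracle. Set sizes are limited to 15–500
after intersection, the method's customary stability window.

**Entity streams.** Enrichment runs once globally, once per compound (its
distinct targets) and once per plant (the union of its compounds' targets).
Each bundle is its own multiple-testing family — pooling across entities
would let a large compound's sets dilute a small one's — and entities with
fewer than 3 genes are flagged `skipped`, never silently dropped. Orphan
genes appear only in the global bundle. Shared-target analysis is exact set
algebra over the plant → target mapping: intersection across all plants,
uniques per plant, pairwise overlap counts.

## The synthetic fixtures: what they emulate, and what passing tests show

`generate_relationships()` emulates the structure of the reference dataset
the package is benchmarked on: 111 genes, 32 compounds, 3 plants, with 32.4%
of compounds in more than one plant, 28.7% of genes under more than one
compound, and 8.1% orphan genes. Counts are placed exactly (rounded targets)
rather than drawn Bernoulli-style, so seeded runs are byte-identical and the
acceptance checks are deterministic given the seed. A common core (default 10
genes) is guaranteed to be — and to be the only genes — targeted by all
plants: one designated compound carries every plant and only core genes may
link to it, while each remaining gene is assigned a forbidden plant and only
links compounds avoiding it. Remaining links are drawn uniformly under these
constraints, with multi-compound genes taking 2–5 compounds.

The generator does *not* emulate realistic phytochemistry: no compound
classes, no dose or affinity structure, no gene–gene correlation, and
expression matrices are i.i.d. Gaussian with an optional planted mean shift.
Passing tests therefore demonstrate that the algorithms implement their
definitions and recover planted structure under clean conditions — not that
real relationship tables, with their synonym noise, ascertainment bias and
correlated pathways, will yield calibrated p-values. The GSEA gene-tag null
in particular is anti-conservative under strong inter-gene correlation.

The fixture's network is also sparser than the reference dataset's reported
edge count: that dataset's 1033 edges cannot coexist with a 28.7%
multi-compound gene fraction over 111 genes, so the generator honors the
fractions (which define the relationship patterns being tested) and lets the
edge count follow. Worked-example checks that depend on specific node and
edge counts construct graphs with exactly those counts instead.

## Problem sizes and runtime choices

Defaults follow the reference protocol: 1000 permutations (GSEA), 1000
randomizations (null tests), FDR 0.05 (ORA), |NES| > 1.0 with FDR 0.25
(GSEA), hub degree 5. The test suite exercises the same algorithms at sizes
chosen for thorough-but-quick coverage: exhaustive ORA enumeration up to a
12-gene universe, GSEA calibration at 200 sets × 200 permutations, planted
recovery over 100 seeded runs, null-model integrity over 20 × 100 replicates,
round-trip serialization over 100 random graphs, and the full 1000-replicate
convergence run on the default fixture. These sizes are the package's own
validation design; the engines themselves carry no hidden limits.

## Reproducibility and outputs

Every random choice — fixture construction, edge swaps, Louvain tie-breaks,
permutation draws, layout coordinates — flows from explicit integer seeds,
recorded in the run manifest together with input digests, the full parameter
set and an inventory of outputs. Networks serialize to GEXF 1.2 and node-link
JSON with the `entity_type` vertex attribute and `layer` edge attribute;
write→read round trips reproduce the typed graph exactly and an invalid graph
is never written. Figures are 300 DPI PNGs with the fixed palette (genes
blue, compounds green, plants pink — the methods-level color contract);
the spring layout's repulsion scales with `1/√density` (floored at 1), the
package's reading of density-adaptive layout, and layout coordinates are
seed-deterministic.

## Known limitations

* No gene-symbol alias mapping, chemical-structure normalization or species
  handling: entities are compared as cleaned strings.
* The null model's layer constraint makes it stricter than an unconstrained
  configuration model; users comparing against literature values derived from
  looser nulls should expect smaller null variance here.
* GSEA's gene-tag permutation ignores inter-gene correlation; GSVA requires
  real expression data and is skipped otherwise.
* Enrichment quality is bounded by the gene-set collections supplied; the
  package ships no databases and performs no online queries.
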