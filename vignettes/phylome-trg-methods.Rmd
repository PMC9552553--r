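---
title: "Phylome reconciliation and TRG discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylome reconciliation and TRG discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylotrg)
```

# Scope

phylotrg implements the analytical core of a phylome-based screen for
taxonomically restricted genes (TRGs): given gene trees for every gene in a
focal genome, it calls speciation and duplication events, maps duplications
onto a species tree, infers gene gains and losses under Dollo parsimony,
searches for the duplication-minimizing species topology, and runs a
multi-evidence filtering cascade (orthology consensus, outgroup exclusion,
annotation, isoform, expression, reciprocal best hits) that narrows a
proteome to a small set of conserved genes of unknown function. Sequence
alignment, maximum-likelihood tree inference, transcriptome assembly and
domain scanning are upstream of this package and out of its scope: it
consumes their outputs (newick trees, tabular hits, TSV tables).

# Event calling by species overlap

For a rooted gene tree whose leaves are mapped to species, each internal
node is scored by the overlap of the species sets of its daughter
partitions:

$$\mathrm{score}(v) \;=\;
  \frac{|S_\mathrm{left} \cap S_\mathrm{right}|}
       {|S_\mathrm{left} \cup S_\mathrm{right}|} \in [0,1].$$

A node is a **duplication** when the score exceeds the overlap cutoff
(default 0: any shared species implies a duplication, the plain
species-overlap rule) and a **speciation** otherwise. Raising the cutoff can
only reclassify duplications as speciations, so duplication counts are
monotonically non-increasing in the cutoff; this is asserted as a property
test. Multifurcating nodes are scored over all pairs of child partitions and
called duplications if any pair overlaps — a conservative generalization of
the binary rule. `annotate_events()` is validated against a brute-force
implementation that recomputes every leaf set from scratch through an
independent traversal.

Orthology and paralogy follow from the events: two genes from different
species are orthologs when the event at their gene-tree MRCA is a
speciation, paralogs when it is a duplication. One-to-one versus
one-to-many/many-to-many is decided by counting, within the MRCA's subtree,
how many sequences each side's species contributes.

## Rooting

Gene trees arriving unrooted can be rooted by midpoint, by the leaf farthest
from the phylome seed sequence, or — the default used everywhere duplications
are counted — by the rooting that minimizes the species-overlap duplication
count over an exhaustive enumeration of all edge rootings. Ties are broken
by the lexicographically smallest canonical newick, so rooting is
deterministic. Exhaustiveness is cheap (2n−3 rootings) and is itself the
oracle used in tests.

# Duplication mapping, ratios, and gains/losses

Each duplication node is dated to the species-tree MRCA of the union of its
daughter species sets. The per-node **duplication ratio** divides the
duplications mapped to a node by the number of gene trees *containing* that
node; 0 means no duplication, 1 an average of one duplication per gene, >1
recurrent duplication. Two decisions here were genuinely open:

* **Containment.** A gene tree is counted as containing an internal species
  node when its species set intersects at least two of the node's daughter
  clades — exactly the trees in which a duplication *could* map to that
  node. The looser reading (any intersection with the node's clade) is
  available via `containment = "clade"`; the strict rule is the default
  because it keeps the denominator interpretable as "trees informative for
  this node". Nodes contained by no tree get an undefined ratio (`NA`),
  never 0.
* **Large expansions.** Duplication rates are often reported with large
  lineage-specific expansions excluded. There is no canonical definition of
  "large expansion" at the gene-tree level, so the package implements it as
  a per-tree, per-node cap (`expansion_cap`, default off, suggested 3) on
  the duplications a single family may contribute to a node. The cap is a
  declared stand-in and is configurable precisely because the concept is
  informal.

**Gain/loss inference** is single-gain Dollo parsimony on ortholog presence
patterns: a family is gained once at the MRCA of the species carrying it,
and losses are placed at the highest nodes whose entire subtree lacks the
family while the parent's subtree does not. Reporting losses only at these
maximal absent subtrees makes the loss set minimal and avoids double
counting; minimality is verified against exhaustive enumeration of loss-node
subsets on trees of up to 8 species.

# The duplication-minimizing species tree

The supertree criterion scores a candidate rooted species topology by the
total number of reconciliation duplications over the gene-tree collection.
Scoring uses the classical LCA mapping: gene-tree node $v$ is a duplication
iff its species-tree image equals the image of one of its children. This is
deliberately *not* the species-overlap rule — species overlap never consults
the species tree, so it cannot discriminate topologies; LCA reconciliation
is the criterion a duplication-minimizing search actually optimizes. The
two rules agree that any overlap-positive node is a duplication; LCA
reconciliation additionally penalizes gene-tree/species-tree discordance.

Gene trees are treated as unrooted: each is given the rooting minimizing its
own duplication count against the candidate (the natural reading when the
upstream pipeline roots trees independently of any species tree). Exhaustive
search enumerates all (2n−3)!! rooted topologies by sequential taxon
insertion and refuses more than 7 taxa; beyond that, a deterministic
hill-climb over rooted NNI rearrangements from a stated start (default: the
caterpillar over the given taxon order) is provided, with lexicographic
newick tie-breaking. Because per-family rooting is optimized, recovery of a
simulating topology is identifiable only up to unrooted equivalence, and the
tests compare unrooted topologies. Exhaustive optimality is checked against
an independent enumeration of the topology space (phangorn's `allTrees`).

Single-copy marker selection (`select_single_copy`) implements the
"one-to-one orthologs in at least *k* of *N* species" rule (the study design
uses 14 of 15), and `concatenate()` builds the supermatrix with 0-based
half-open partitions and gap masking for absent taxa; downstream ML
inference on the supermatrix is intentionally left to external tools.

# The TRG filtering cascade

Stages run in a fixed order, each consuming the survivors of the previous
one, with every removal logged in a filter trace:

1. **Consensus orthology**: a candidate passes when every required tool
   reports a one-to-one ortholog in every ingroup species. The tool registry
   is per species pair, because real tool suites are incomplete (in the
   motivating study OMA never ran against the two non-urchin echinoderms);
   the default requires all registered tools.
2. **Outgroup exclusion**: any call by any tool to any outgroup species
   disqualifies a candidate. The rule is deliberately "any evidence"
   rather than "any one-to-one call": the screen is for genes with *no*
   detectable homology outside the ingroup.
3. **Unannotated only**: genes with any ontology term, or any
   transposable-element domain, are removed; genes absent from the
   annotation table count as unannotated.
4. **Longest isoform**: candidates that are isoform-level protein models
   are collapsed to their gene's longest isoform (ties by ascending isoform
   ID).
5. **Expression**: peak TPM strictly greater than 50 across the
   developmental time course (0–72 h post-fertilization on the nine-point
   grid). The threshold is the rule; "top decile of the dataset" is a
   diagnostic observation about one dataset, not a second filter. The
   boundary is strict: a peak of exactly 50 is removed.
6. **Evidence report**: reciprocal best hits against one or more reference
   proteomes (priority order declared by the caller), report-level ontology,
   and phylome-tree presence are tabulated per surviving gene, with the
   headline counts (total, with RBBH, without ontology, with/without tree,
   zero-evidence).

Similarity-hit filtering (`filter_hits`) retains hits with e-value strictly
below 1e-5 whose single contiguous aligned segment covers at least 50% of
the query, then caps each query at its 150 closest hits (smallest e-value;
ties by bit score, then subject ID). Coverage is computed from one hit
record's query span — no chaining of multiple HSPs — which is the simplest
faithful reading of "continuous overlap". Reciprocal best hits use the
relaxed 1e-7 bound and require mutual *unique* bests: a tie unresolved by
e-value and bit score makes the query ambiguous and produces no pair, so an
RBBH never depends on input order; symmetry of the pair set under exchanging
the two tables is a property test.

The filter stage and the report may draw on different annotation sources
(`report_annotations`): the screen filters on PFAM-derived ontology, while
the final table reports a full InterProScan scan, which is how a reported
gene can legitimately carry GO terms.

# GO enrichment and selection summaries

`go_enrichment()` tests each term's 2×2 table with the hypergeometric
distribution (one-sided over-representation by default, the standard
FatiGO-style use; two-sided via Fisher's exact test on request) and adjusts
across terms by Benjamini–Hochberg. The multiple-testing procedure was an
open choice; BH is the field default for exploratory term screens. P-values
are validated to 1e-12 against an explicit summation of the hypergeometric
mass function. `selection_summary()` counts sites whose posterior
probability of positive or negative selection meets the threshold
(inclusive, default 0.95 — the conventional reporting cutoff for
FUBAR-style site tables) and reports percentages to one decimal.

# Synthetic data: what it emulates, and what it does not

The simulators provide ground truth for every stage:

* `simulate_species_tree()` draws uniformly from rooted labelled topologies
  by sequential random insertion.
* `simulate_family()` evolves one ancestral copy along the species tree;
  on each branch every entering copy duplicates with probability λ (one
  event per copy per branch, logged on that branch) and each resulting
  lineage is lost with probability μ. The branch-discrete model was chosen
  over continuous-time birth–death because it gives exact event bookkeeping
  and closed-form expectations (with μ = 0 the expected duplication total is
  $\lambda \sum_b E[\text{copies entering } b]$), which the Monte Carlo
  tests check within three standard errors. Families that go extinct are
  re-drawn and counted. With μ = 0, reconciliation recovers the simulator's
  per-node duplication counts exactly; this is asserted over hundreds of
  random (topology, λ) settings.
* `simulate_calls()` emits every true one-to-one ortholog pair per tool and
  drops each pair independently with the tool's false-negative rate (the
  pair, not the direction, is the error unit), plus spurious cross-species
  calls at a false-positive rate.
* `simulate_expression()` produces unimodal Gaussian-in-time profiles with
  peak times between 18 and 24 h and plants an exact count of genes above
  the 50-TPM threshold — exact planting keeps cascade tests non-flaky.
* `simulate_study()` assembles a full cascade input bundle with layer sizes
  defaulting to the published screen's trace (200 → 145 → 31 → 14) and a
  planted TRG set that the cascade must recover exactly at zero tool error.

What the synthetic data does **not** emulate: sequence-level evolution (no
residues are simulated, so alignment- and similarity-derived artifacts are
outside the tests' reach), correlated tool errors (real orthology tools fail
on the same hard families, not independently), compositional biases of real
expression data, and continuous-time duplication/loss. Passing tests
therefore demonstrate algorithmic correctness on the declared models, not
robustness to every pathology of real proteomes.

# Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally; the 12-column tabular hit
  format keeps its native 1-based inclusive query/subject spans.
* All threshold comparisons are as documented: e-value and TPM strictly
  below/above, selection posteriors inclusive.
* Ratios with zero denominators (duplication ratio at an uncontained node,
  percentages for a gene with no sites) are `NA`, never 0.
* Ties are always broken deterministically (bit score then subject ID for
  hits; ascending isoform ID; lexicographic canonical newick for
  topologies and rootings).
* Unmappable gene-tree leaves, unknown orthology tools, negative TPMs,
  posteriors outside [0, 1], and empty presence rows are errors that name
  the offending record, never silent drops.

# Problem sizes in the shipped test suite

The default suite runs entirely from code-generated fixtures: 250 random
trees for newick round-trips, 150 random gene trees (≤12 leaves) for the
species-overlap oracle, 500 loss-free simulated families for exact event
recovery, 200 families for conservation, 40 exhaustive Dollo checks (≤8
species), 36 exhaustive supertree optimality checks (4–6 taxa), 10,000
draws for topology uniformity, 230 random hypergeometric tables, and ~100
small synthetic cascade studies across tool-error rates. These sizes were
chosen so the full suite exercises every property at statistical depth
while remaining comfortably runnable on a laptop.

# Known limitations

* The species-overlap caller ignores branch lengths and support values;
  poorly supported nodes are treated as confidently resolved.
* The NNI search is a single deterministic hill-climb; it guarantees a
  local optimum no worse than the start, not a global one.
* Dollo inference assumes orthogroup presence calls are correct; it has no
  error model for missed orthologs (a missed call becomes a spurious loss).
* The expansion cap is a pragmatic stand-in for an informal concept and
  should be reported alongside any capped duplication rates.
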