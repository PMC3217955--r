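---
title: "Ortholog-based GO annotation transfer and enrichment: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ortholog-based GO annotation transfer and enrichment: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthogo)
```

# The problem

Gene Ontology (GO) annotation concentrates in a handful of intensively
curated model genomes.  For a genus of closely related species — the
motivating case is filamentous fungi, where one model species carries a
genome-scale, partly manually curated annotation while its congeners have
none — the practical route to usable functional annotation is homology:
identify orthologous (and closely paralogous) protein groups across the
genomes and let every group member inherit the reference member's GO
terms.  Once each genome has an annotation, study gene lists from omics
experiments can be screened for over-represented GO terms with standard
enrichment statistics, and results for orthologous gene sets can be
compared across species.

`orthogo` implements that pipeline as four cooperating layers: an
ontology layer (OBO parsing, DAG closure operations), a clustering layer
(two-step Jaccard / reciprocal-best-hit ortholog detection), a transfer
layer (annotation projection and file formats) and an enrichment layer
(Fisher's exact test with FDR control and GO-slim summaries).  A fifth
layer generates deterministic synthetic data so every stage is testable
without any external downloads.

# The ontology layer

GO terms form three rooted directed acyclic graphs (biological process,
molecular function, cellular component).  `parse_obo()` loads OBO 1.2
text, keeping `is_a` and `part_of` edges — the two relations whose
semantics license the *true-path rule* (a gene annotated to a term is
implicitly annotated to all the term's ancestors).  Regulates-type edges
do not carry that implication and are never loaded.  Obsolete terms are
retained and flagged but carry no edges and never receive or propagate
annotation; alternative ids are resolved to primary ids at parse time, so
every downstream operation sees primary ids only.

`propagate()` applies the true-path rule to an annotation table: each
gene's term set is replaced by its ancestor closure.  The operation is
idempotent, and its output is what both the distinct-term summaries and
the enrichment statistics consume.  Two reductions complete the layer:

* `reduce_to_most_specific()` removes every term that is an ancestor of
  another term in the same set, leaving an antichain.  Enrichment results
  are redundant along ancestor chains (a significant leaf usually drags
  several ancestors over the threshold); the antichain is the informative
  part.
* `slim_count()` maps a term set onto a GO slim with *single-occurrence*
  counting: per input term, each slim term that equals it or sits among
  its ancestors is credited once, regardless of how many paths lead
  there.  This makes slim counts insensitive to the multiplicity of
  diamond structures in the DAG.

Whether propagated distinct-term counts should include the three root
terms is genuinely ambiguous in summary tables of this kind (every
annotated gene trivially reaches the roots).  Propagation always includes
them; the counting functions take a `drop_roots` flag, with the default
(include) matching the convention that reproduces the published
per-genome term counts.

# The clustering layer

The ortholog detector is a two-step procedure over an all-vs-all protein
similarity search (12-column tabular hits; the search itself is out of
scope).

**Step 1 — within-genome paralog families.**  Hits are kept at E-value
≤ 1e-5, and the within-genome stage additionally requires percent
identity ≥ 80 and discards self-hits.  The *match set* of a polypeptide
is itself plus every same-genome polypeptide it hits or is hit by
(symmetrised over direction — a protein that only ever appears as a
subject still gets a well-defined match set; including the protein itself
reflects the near-universal self-hit).  Every distinct pair is scored
with the Jaccard coefficient of its match sets, pairs with J *strictly*
greater than 0.6 are connected, and graph components become Jaccard
clusters.  All three thresholds are exposed in `clustering_params()` with
those defaults.

**Step 2 — cross-genome linking.**  For the cross-genome stage only the
E-value filter applies.  Cluster A (genome GA) and cluster B (genome GB)
are linked iff some member of A has its maximal-bitscore hit in GB inside
B *and* vice versa — cluster-level reciprocal best hits.  Bitscore, not
E-value, ranks hits (E-values tie at the floor); ties retain all tied
subjects, which keeps the procedure deterministic and independent of
input file order.  Any polypeptide pair may witness the two directions;
the criterion is cluster-level.  Components of the resulting cluster
graph with at least two clusters are Jaccard orthologous clusters.
Because components may chain through several clusters, a component can
contain more than one cluster from the same genome — deliberate, as the
groups are intended to capture orthologs *and* close paralogs.  Isolated
clusters are reported as unclustered rather than silently dropped.

Properties the test suite pins down: Jaccard clusters partition each
proteome; raising the threshold refines the partition; the edge set is
symmetric in the genome labels; and the complete two-step result equals a
naive all-pairs/union-find re-derivation on randomized instances.

# The transfer layer

`transfer_annotations()` gives every member of an orthologous cluster the
identical direct term set: the union of the direct annotations of the
cluster's reference-genome members.  Union is the only loss-free choice
compatible with "all members share identical terms" when a cluster holds
several annotated reference genes.  Transferred records carry the IEA
evidence code with the source gene ids in the GAF With/From column, so
the provenance of every projected term is recoverable.  By default the
reference genome itself also adopts the cluster-level union (cross-genome
consistency); `keep_reference_direct = TRUE` preserves its curated sets
instead.  Annotated reference genes outside any cluster are counted and
reported as unmapped.

Annotation IO covers GAF 2.x (17 columns, `NOT`-qualified rows excluded
on parsing), GMT and a simple gene-to-terms table.  Writers emit sorted
rows and take the GAF date from a fixed table attribute, making output
byte-deterministic — re-running a pipeline on identical input yields
identical files.  Percentages in every summary use plain `round()`; this
convention reproduces the published per-strain annotated percentages and
coverage figures from the bundled `table1_fixture()` rows.  (The one
published share it does not hit exactly is the biological-process share,
printed as 55% where exact arithmetic gives 55.57 → 56; the printed
shares were evidently nudged to sum to 100.)

# The enrichment layer

For a study set of *n* genes from a universe of *N*, of which *K* carry a
term (after propagation) and *k* in the study set, the one-tailed
Fisher's exact test is the hypergeometric upper tail
$p = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$,
computed via the exact distribution function (and verified in the tests
against brute-force enumeration of all outcomes for every valid
configuration with N ≤ 12).  Benjamini–Hochberg adjustment is
implemented by the step-up formula
$q_{(i)} = \min_{j \ge i} \; m\,p_{(j)}/j$ and cross-checked against the
standard library implementation.

Decisions a user can override, with the defaults and their rationale:

* **Universe** (`annotated_only`, default): genes with at least one
  propagated term.  Unannotated genes carry no information for a
  term-frequency test and only deflate p-values artificially; the
  `all_predicted` policy is provided for comparability with tools that
  count every predicted gene.
* **Candidate family**: terms with k ≥ `min_study_count` (default 1).
  Terms untouched by the study set cannot be over-represented; excluding
  them keeps the BH family relevant.
* **Correction scope** (`joint`, default): one BH family across all three
  namespaces; `per_namespace` is available for workflows that analyse a
  single ontology branch.
* **Significance**: q ≤ alpha (default 0.05), boundary inclusive.
* Unknown study ids are tallied and attached to the result, never
  silently discarded, so *n* is always well defined; only
  over-representation is tested.

`slim_comparison()` maps several labelled significant-term lists onto one
slim and returns the slim-term × label count matrix used to compare
enrichment results across species.  `export_results()` writes the full
record table (TSV), a text digest, and per-namespace DOT graphs of the
significant terms plus their ancestors (significant nodes filled,
`part_of` edges dashed); the DOT files render directly to SVG with
standard tools.

# Synthetic data: what it emulates and what it does not

`fixture_spec()` drives all generators from one integer seed (ontology
from `seed`, proteomes/hits from `seed + 1`, annotation from `seed + 2`);
outputs are pure functions of the spec object and leave the caller's RNG
stream
untouched.

* `make_ontology()` builds three namespaces as rooted b-ary trees of
  configurable depth plus a seeded fraction of two-parent "diamond"
  nodes; level-2 terms are tagged as a slim subset.
* `make_proteomes_hits()` plants 1:1:…:1 ortholog groups (reciprocal
  cross-genome hits whose bitscores strictly dominate all noise by a
  fixed margin, avoiding accidental ties) and within-genome paralog
  families (complete hit graphs at identity ≥ 80, giving pairwise J = 1),
  then adds noise hits that fail the identity filter or rank below the
  planted scores.  At zero noise the planted structure is recovered
  exactly — by construction, and asserted in the tests.
* `make_annotation()` assigns each leaf term to each gene with a
  configurable background probability (default 5%) and plants one leaf
  term on a designated carrier subset, creating a known enrichment
  effect.  The default study conditions used in the recovery checks —
  universe 2,000 genes, 5% background rate, studies of 50 genes with 20
  carriers — are the regime the enrichment layer targets.

These generators produce clean block structure: no sequence evolution, no
realistic E-value model, no partial-overlap paralogy, no annotation bias
toward well-studied genes.  Passing the planted-recovery tests therefore
demonstrates correctness of the algorithms under their own assumptions,
not robustness to the messiness of real similarity searches — the
published caveat that the graph-based approach degrades for many
distantly related genomes or highly repetitive proteomes applies
unchanged.

# Numerical and scale choices

Problem sizes in the test suite are chosen to make the oracles exhaustive
where feasible and the stochastic checks statistically meaningful: Fisher
against full enumeration for all N ≤ 12; BH against the reference
implementation on 1,000 random vectors; clustering against the naive
oracle on 100 random instances of up to 4 genomes × 15 proteins; DAG
closure against DFS enumeration on 200 random DAGs of up to 30 nodes;
type-I control over 1,000 random study sets (the family-wise detection
rate must stay below α + 3·√(α/runs), a three-sigma band around the BH
guarantee); and planted-signal recovery over 100 independently seeded
simulations with a ≥ 95% recovery requirement.  The acceptance script
uses 50 recovery runs and 400 null runs, which keeps its full runtime
under a minute while leaving the empirical rates' standard errors well
inside the slack of the pass bands.

Other numeric conventions: J is 0 on an empty union; all filter
boundaries are inclusive except the Jaccard threshold (strict, as
specified by the procedure's published default); duplicate (query,
subject) hit pairs keep the maximal-bitscore record; cluster and
component identifiers are assigned by sorted smallest member, so all
outputs are independent of input order.

# Known limitations

* Orthology is purely graph-based on similarity hits; no synteny, no
  gene trees.  Transfer quality is bounded by the reference's curation
  and by clustering correctness.
* Only `is_a` and `part_of` are traversed; ontologies whose semantics
  require regulates-edges are out of scope.
* Under-representation is not tested, and the enrichment model treats
  genes as exchangeable — no gene-length or expression-level bias
  correction.
* The GAF writer fills non-essential columns (symbol, taxon, reference)
  with placeholders; round-trips preserve the data model (gene, term,
  evidence, with/from), not arbitrary third-party GAF columns.
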