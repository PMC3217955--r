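Package: orthogo
Title: Ortholog-Based Transfer of Gene Ontology Annotation and GO Term
    Enrichment Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extends Gene Ontology (GO) annotation from a well-annotated
    reference genome to related genomes via a two-step clustering of
    all-vs-all protein similarity hits: within-genome paralog families are
    built from Jaccard coefficients of BLASTP match sets, and families are
    linked across genomes by cluster-level reciprocal best hits.  Cluster
    members inherit the reference annotation, which is written out in GAF,
    GMT and gene-to-terms formats.  A GO term enrichment module implements
    the one-tailed Fisher's exact (hypergeometric) test with
    Benjamini-Hochberg false discovery rate control, reduction of enriched
    terms to the most specific subset, and GO-slim occurrence summaries for
    comparing enrichment results across species.  Includes an OBO parser,
    true-path annotation propagation, deterministic synthetic-fixture
    generators with planted ortholog groups and enrichment signal, and a
    command-line pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
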