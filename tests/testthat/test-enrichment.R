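test_that("one-tailed Fisher matches the hypergeometric upper tail", {
  expect_equal(one_tailed_fisher(0, 3, 4, 10), 1)       # whole distribution
  expect_equal(one_tailed_fisher(3, 10, 3, 10), 1)      # study = universe
  expect_equal(one_tailed_fisher(2, 3, 3, 10), 22 / 120,
               tolerance = 1e-12)
  # p is non-increasing in k for fixed (n, K, N)
  p <- one_tailed_fisher(0:5, 8, 5, 30)
  expect_true(all(diff(p) <= 0))
  # domain errors
  expect_error(one_tailed_fisher(4, 3, 5, 10), "invalid")
  expect_error(one_tailed_fisher(1, 3, 11, 10), "invalid")
})

test_that("Benjamini-Hochberg step-up adjusts and preserves order", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
  set.seed(42)
  p <- runif(50)
  q <- benjamini_hochberg(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # permutation equivariance
  perm <- sample(50)
  expect_equal(benjamini_hochberg(p[perm]), q[perm])
})

# ontology + universe with a perfectly enriched leaf term
enrich_fixture <- function() {
  g <- toy_ontology(
    list("GO:0000005" = character(),
         "GO:0000004" = c("GO:0000005" = "is_a"),
         "GO:0000001" = c("GO:0000004" = "is_a"),
         "GO:0000002" = c("GO:0000004" = "is_a"),
         "GO:0000003" = c("GO:0000005" = "is_a")))
  genes <- sprintf("gene%03d", 1:60)
  rec <- data.frame(gene = genes,
                    term = rep(c("GO:0000001", "GO:0000002", "GO:0000003"),
                               each = 20),
                    stringsAsFactors = FALSE)
  list(graph = g, background = annotation_table(rec), genes = genes)
}

test_that("a perfectly enriched leaf is significant and most specific", {
  fx <- enrich_fixture()
  study <- fx$genes[1:20]   # exactly the GO:0000001 carriers
  res <- enrich(study, fx$background, fx$graph)
  row <- res[res$term == "GO:0000001", ]
  expect_equal(row$k, 20); expect_equal(row$K, 20)
  expect_equal(row$n, 20); expect_equal(row$N, 60)
  expect_true(row$significant)
  expect_true(row$most_specific)
  # its ancestor GO:0000004 is significant too (k=20 of K=40) but the
  # reduction keeps only the leaf
  anc <- res[res$term == "GO:0000004", ]
  expect_true(anc$significant)
  expect_false(anc$most_specific)
  expect_equal(res$term[res$most_specific], "GO:0000001")
  # root is untestworthy (K = N) but still p = 1, never significant
  expect_false(res$significant[res$term == "GO:0000005"])
})

test_that("enrichment counts respect the DAG after propagation", {
  fx <- enrich_fixture()
  res <- enrich(fx$genes[c(1:25, 41:45)], fx$background, fx$graph,
                enrichment_params(alpha = 1))
  get <- function(term, col) res[res$term == term, col]
  edges <- list(c("GO:0000001", "GO:0000004"),
                c("GO:0000004", "GO:0000005"),
                c("GO:0000003", "GO:0000005"))
  for (e in edges) {
    expect_gte(get(e[2], "k"), get(e[1], "k"))
    expect_gte(get(e[2], "K"), get(e[1], "K"))
  }
  # alpha = 1 makes every candidate significant (q <= 1 always)
  expect_true(all(res$significant))
})

test_that("unknown study ids are tallied, empty mappings are fatal", {
  fx <- enrich_fixture()
  res <- enrich(c(fx$genes[1:5], "nosuch1", "nosuch2"), fx$background,
                fx$graph)
  expect_setequal(attr(res, "unknown_ids"), c("nosuch1", "nosuch2"))
  expect_equal(attr(res, "n_study"), 5)
  expect_error(enrich(c("nosuch1"), fx$background, fx$graph),
               "no study gene")
})

test_that("universe policy switches between annotated and all predicted", {
  fx <- enrich_fixture()
  proteome <- data.frame(genome = "gX",
                         protein = c(fx$genes, sprintf("extra%02d", 1:40)),
                         stringsAsFactors = FALSE)
  res_ann <- enrich(fx$genes[1:20], fx$background, fx$graph)
  expect_equal(attr(res_ann, "universe_size"), 60)
  res_all <- enrich(fx$genes[1:20], fx$background, fx$graph,
                    enrichment_params(universe = "all_predicted"),
                    proteome = proteome)
  expect_equal(attr(res_all, "universe_size"), 100)
  expect_error(enrich(fx$genes[1:20], fx$background, fx$graph,
                      enrichment_params(universe = "all_predicted")),
               "needs a proteome")
})

test_that("per-namespace correction adjusts within namespaces", {
  spec <- fixture_spec(seed = 31, depth = 3, branching = 3,
                       background_rate = 0.2, n_carriers = 15)
  g <- make_ontology(spec)
  genes <- sprintf("g%03d", 1:200)
  ann <- make_annotation(spec, g, genes)
  study <- c(attr(ann, "carriers"),
             setdiff(unique(ann$records$gene), attr(ann, "carriers"))[1:10])
  joint <- enrich(study, ann, g)
  perns <- enrich(study, ann, g,
                  enrichment_params(correction = "per_namespace"))
  expect_setequal(joint$term, perns$term)
  for (ns in unique(perns$namespace)) {
    i <- perns$namespace == ns
    expect_equal(perns$q[i], benjamini_hochberg(perns$p[i]))
  }
})

test_that("slim comparison assembles per-label single-occurrence counts", {
  spec <- fixture_spec(seed = 17, depth = 4, branching = 2)
  g <- make_ontology(spec)
  slim <- slim_from_subset(g, "goslim_synthetic")
  bp_leaves <- leaf_terms(g, "biological_process")
  sets <- list(s1 = bp_leaves[1:3], s2 = bp_leaves[1:3], s3 = bp_leaves[1:3])
  mat <- slim_comparison(sets, slim, g)
  expect_equal(dim(mat), c(length(slim$members), 3))
  expect_identical(mat[, "s1"], mat[, "s2"])
  expect_identical(mat[, "s1"], mat[, "s3"])
  # empty set gives a zero column; a changed branch shows up in one row
  mat2 <- slim_comparison(list(a = bp_leaves[1:3], b = character()), slim, g)
  expect_true(all(mat2[, "b"] == 0))
  mf_leaf <- leaf_terms(g, "molecular_function")[1]
  mat3 <- slim_comparison(list(a = bp_leaves[1:2],
                               b = c(bp_leaves[1:2], mf_leaf)), slim, g)
  diff_rows <- rownames(mat3)[mat3[, "a"] != mat3[, "b"]]
  expect_true(all(g$namespace[diff_rows] == "molecular_function"))
  expect_error(slim_comparison(list(), slim, g), "at least one")
  expect_error(slim_comparison(setNames(sets, c("x", "x", "y")), slim, g),
               "duplicate")
})

test_that("export writes a result TSV, summary and renderable DOT graphs", {
  fx <- enrich_fixture()
  res <- enrich(fx$genes[1:20], fx$background, fx$graph)
  prefix <- file.path(withr::local_tempdir(), "run")
  paths <- export_results(res, fx$graph, prefix)
  tsv <- utils::read.delim(paste0(prefix, "_enrichment.tsv"))
  expect_equal(nrow(tsv), nrow(res))
  expect_true(file.exists(paste0(prefix, "_summary.txt")))
  dot <- readLines(paste0(prefix, "_biological_process.dot"))
  expect_equal(dot[1], "digraph \"biological_process\" {")
  expect_equal(dot[length(dot)], "}")
  # significant leaf plus its ancestor chain are the nodes
  expect_true(any(grepl("GO:0000001", dot)))
  expect_true(any(grepl("GO:0000005", dot)))
  expect_true(any(grepl("GO:0000001.*->.*GO:0000004", dot)))
  expect_true(any(grepl("lightblue", dot)))
  # other namespaces have empty graphs
  mf <- readLines(paste0(prefix, "_molecular_function.dot"))
  expect_false(any(grepl("GO:", mf)))
})

test_that("zero significant terms still produce valid empty outputs", {
  fx <- enrich_fixture()
  # uniform draw across all three blocks: no term enriched
  study <- fx$genes[c(1:3, 21:23, 41:43)]
  res <- enrich(study, fx$background, fx$graph,
                enrichment_params(alpha = 0.001))
  expect_false(any(res$significant))
  prefix <- file.path(withr::local_tempdir(), "null")
  export_results(res, fx$graph, prefix)
  dot <- readLines(paste0(prefix, "_biological_process.dot"))
  expect_false(any(grepl("GO:", dot)))
})
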