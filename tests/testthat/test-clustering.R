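mk_hit <- function(q, s, pident = 90, evalue = 1e-20, bitscore = 500) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = 100L,
             mismatch = 5L, gapopen = 1L, qstart = 1L, qend = 100L,
             sstart = 1L, send = 100L, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

two_genomes <- data.frame(
  genome = rep(c("gA", "gB"), each = 3),
  protein = c("a1", "a2", "a3", "b1", "b2", "b3"),
  stringsAsFactors = FALSE)

test_that("filter_hits applies inclusive boundaries per stage", {
  hits <- rbind(
    mk_hit("a1", "a2", pident = 80.0, evalue = 1e-5),   # boundary: kept
    mk_hit("a1", "a1", pident = 99, evalue = 1e-30),    # self: dropped
    mk_hit("a2", "a3", pident = 79.9, evalue = 1e-30),  # identity too low
    mk_hit("a1", "b1", pident = 79.9, evalue = 1e-30),  # cross-genome
    mk_hit("a2", "b1", pident = 95, evalue = 1e-4))     # evalue too high
  par <- filter_hits(hits, two_genomes, stage = "paralog")
  expect_equal(nrow(par), 1)
  expect_equal(par$qseqid, "a1")
  expect_equal(par$pident, 80.0)
  orth <- filter_hits(hits, two_genomes, stage = "ortholog")
  expect_equal(nrow(orth), 1)
  expect_equal(orth$sseqid, "b1")
  expect_equal(orth$pident, 79.9)
  expect_error(filter_hits(mk_hit("zz", "a1"), two_genomes),
               "unknown protein")
})

test_that("filter_hits keeps the best-scoring hit per pair", {
  hits <- rbind(mk_hit("a1", "a2", bitscore = 100),
                mk_hit("a1", "a2", bitscore = 300),
                mk_hit("a1", "a2", bitscore = 200))
  par <- filter_hits(hits, two_genomes, stage = "paralog")
  expect_equal(nrow(par), 1)
  expect_equal(par$bitscore, 300)
})

test_that("match sets include self and symmetrise hit direction", {
  prot <- c("a1", "a2", "a3")
  expect_equal(match_sets(prot, mk_hit("a1", "a2"))[["a3"]], "a3")
  ms <- match_sets(prot, mk_hit("a1", "a2"))
  expect_equal(ms[["a1"]], c("a1", "a2"))
  expect_equal(ms[["a2"]], c("a1", "a2"))
  ms2 <- match_sets(prot, rbind(mk_hit("a1", "a2"), mk_hit("a2", "a3")))
  expect_equal(ms2[["a2"]], c("a1", "a2", "a3"))
})

test_that("jaccard coefficient is a bounded symmetric set ratio", {
  expect_equal(jaccard_coefficient(c("x", "y"), c("x", "y")), 1)
  expect_equal(jaccard_coefficient("x", "y"), 0)
  expect_equal(jaccard_coefficient(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(jaccard_coefficient(character(), character()), 0)
  for (i in 1:20) {
    m1 <- sample(letters, sample(1:10, 1))
    m2 <- sample(letters, sample(1:10, 1))
    j <- jaccard_coefficient(m1, m2)
    expect_identical(j, jaccard_coefficient(m2, m1))
    expect_gte(j, 0); expect_lte(j, 1)
  }
})

test_that("Jaccard clustering uses a strict threshold and finds components", {
  # J(A, B) = J(A, C) = 0.6 exactly, J(B, C) = 1: A must stay a singleton
  genome <- data.frame(genome = "gA",
                       protein = c("A", "B", "C", "D", "E"),
                       stringsAsFactors = FALSE)
  hits <- rbind(mk_hit("A", "B"), mk_hit("A", "C"), mk_hit("A", "D"),
                mk_hit("A", "E"), mk_hit("B", "C"))
  msets <- match_sets(genome$protein, hits)
  expect_equal(jaccard_coefficient(msets[["A"]], msets[["B"]]), 0.6)
  jc <- build_jaccard_clusters(hits, genome)
  part <- package_jaccard_partition(jc)$gA
  expect_true(list(c("B", "C")) %in% part ||
                any(vapply(part, identical, logical(1), c("B", "C"))))
  expect_true(any(vapply(part, identical, logical(1), "A")))
  # every protein in exactly one cluster
  expect_setequal(jc$protein, genome$protein)
  expect_false(anyDuplicated(jc$protein) > 0)
  # just under the threshold the 0.6 pairs connect
  jc2 <- build_jaccard_clusters(hits, genome,
                                clustering_params(jaccard_threshold = 0.59))
  part2 <- package_jaccard_partition(jc2)$gA
  expect_true(any(vapply(part2, function(p) all(c("A", "B", "C") %in% p),
                         logical(1))))
})

test_that("a mutually-hitting triple forms one Jaccard cluster", {
  genome <- data.frame(genome = "gA", protein = c("A", "B", "C"),
                       stringsAsFactors = FALSE)
  hits <- rbind(mk_hit("A", "B"), mk_hit("B", "C"), mk_hit("A", "C"))
  jc <- build_jaccard_clusters(hits, genome)
  expect_equal(length(unique(jc$cluster_id)), 1)
})

test_that("best_hits returns all tied top-bitscore subjects", {
  hits <- rbind(mk_hit("a1", "b1", bitscore = 500),
                mk_hit("a1", "b2", bitscore = 400),
                mk_hit("a2", "b2", bitscore = 500),
                mk_hit("a2", "b3", bitscore = 500))
  expect_equal(best_hits("a1", "gB", hits, two_genomes), "b1")
  expect_setequal(best_hits("a2", "gB", hits, two_genomes),
                  c("b2", "b3"))
  expect_setequal(best_hits(c("a1", "a2"), "gB", hits, two_genomes),
                  c("b1", "b2", "b3"))
  expect_equal(best_hits("a3", "gB", hits, two_genomes), character())
})

test_that("rbh edges require reciprocity; components become clusters", {
  jc <- data.frame(cluster_id = c("gA.JC0001", "gB.JC0001"),
                   genome = c("gA", "gB"), protein = c("a1", "b1"),
                   stringsAsFactors = FALSE)
  one_way <- mk_hit("a1", "b1")
  expect_equal(nrow(rbh_cluster_edges(jc, one_way, two_genomes)), 0)
  mutual <- rbind(mk_hit("a1", "b1"), mk_hit("b1", "a1"))
  edges <- rbh_cluster_edges(jc, mutual, two_genomes)
  expect_equal(nrow(edges), 1)

  oc0 <- build_ortholog_clusters(jc, edges[0, ])
  expect_equal(nrow(oc0$clusters), 0)
  expect_length(oc0$unclustered, 2)

  # chain of three clusters across three genomes -> one ortholog cluster
  chain_edges <- data.frame(a = c("gA.JC0001", "gB.JC0001"),
                            b = c("gB.JC0001", "gC.JC0001"),
                            stringsAsFactors = FALSE)
  jc3 <- rbind(jc, data.frame(cluster_id = "gC.JC0001", genome = "gC",
                              protein = "c1", stringsAsFactors = FALSE))
  oc <- build_ortholog_clusters(jc3, chain_edges)
  expect_equal(length(unique(oc$clusters$ortholog_id)), 1)
  expect_setequal(oc$clusters$protein, c("a1", "b1", "c1"))
})

test_that("planted 1:1:1 orthologs across three genomes form a triangle", {
  spec <- fixture_spec(seed = 5, n_genomes = 3, proteins_per_genome = 4,
                       n_ortholog_groups = 1,
                       paralog_family_sizes = integer(),
                       noise_hit_rate = 0)
  ph <- make_proteomes_hits(spec)
  jc <- build_jaccard_clusters(ph$hits, ph$proteomes)
  ohits <- filter_hits(ph$hits, ph$proteomes, stage = "ortholog")
  edges <- rbh_cluster_edges(jc, ohits, ph$proteomes)
  grp <- ph$truth$ortholog_groups$protein
  cmap <- structure(jc$cluster_id, names = jc$protein)
  in_group <- sort(unique(unname(cmap[grp])))
  tri <- edges[edges$a %in% in_group & edges$b %in% in_group, ]
  expect_equal(nrow(tri), 3)   # triangle over the three genomes
})

test_that("clustering summaries report counts and rounded percentages", {
  spec <- fixture_spec(seed = 9, n_genomes = 2, proteins_per_genome = 5,
                       n_ortholog_groups = 3,
                       paralog_family_sizes = integer(),
                       noise_hit_rate = 0)
  ph <- make_proteomes_hits(spec)
  res <- cluster_proteomes(ph$hits, ph$proteomes)
  s <- res$summary
  expect_equal(s$clustered[s$genome == "total"], 6)
  expect_equal(s$percent[s$genome == "total"], 60)
  expect_equal(attr(s, "n_clusters"), 3)

  empty <- build_ortholog_clusters(res$jaccard,
                                   data.frame(a = character(),
                                              b = character()))
  s0 <- clustering_summary(empty, ph$proteomes)
  expect_equal(s0$clustered[s0$genome == "total"], 0)
  expect_equal(s0$percent[s0$genome == "total"], 0)
  expect_equal(attr(s0, "n_clusters"), 0)
})

test_that("hit tables and cluster tables round-trip through disk", {
  spec <- fixture_spec(seed = 13, noise_hit_rate = 0.2)
  ph <- make_proteomes_hits(spec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits(ph$hits, path)
  back <- read_blast_tab(path)
  expect_equal(back$qseqid, ph$hits$qseqid)
  expect_equal(back$bitscore, ph$hits$bitscore, tolerance = 1e-12)

  res <- cluster_proteomes(ph$hits, ph$proteomes)
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_clusters(res$ortholog, cpath)
  oc2 <- read_clusters(cpath)
  expect_s3_class(oc2, "ortholog_clusters")
  expect_equal(oc2$clusters, res$ortholog$clusters)
})

test_that("raising the Jaccard threshold refines the partition", {
  for (seed in 1:5) {
    set.seed(seed)
    inst <- random_cluster_instance()
    loose <- build_jaccard_clusters(inst$hits, inst$proteomes,
                                    clustering_params(jaccard_threshold = 0.3))
    tight <- build_jaccard_clusters(inst$hits, inst$proteomes,
                                    clustering_params(jaccard_threshold = 0.7))
    loose_of <- structure(loose$cluster_id, names = loose$protein)
    for (cl in split(tight$protein, tight$cluster_id)) {
      expect_length(unique(loose_of[cl]), 1)
    }
  }
})
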