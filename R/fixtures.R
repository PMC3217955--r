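# Deterministic generators for toy ontologies, proteomes, similarity hits
# with planted ortholog/paralog structure, annotation tables with planted
# enrichment signal, and the printed reference mapping table.

# Run expr under a seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Fixture specification
#'
#' One integer seed drives every sub-generator through a fixed splitting
#' scheme: the ontology draws from `seed`, proteomes/hits from `seed + 1`,
#' and annotation from `seed + 2`.
#'
#' @param seed integer master seed.
#' @param n_genomes number of genomes.
#' @param proteins_per_genome proteins per genome.
#' @param n_ortholog_groups planted 1:1:...:1 ortholog groups (one member
#'   per genome).
#' @param paralog_family_sizes integer vector; each genome gets one planted
#'   paralog family per entry, of that size.
#' @param noise_hit_rate expected number of random noise hits per protein.
#' @param depth ontology depth per namespace (1 = root only).
#' @param branching children per internal ontology node.
#' @param diamond_fraction fraction of eligible nodes receiving a second
#'   parent (multi-parent "diamond" nodes).
#' @param background_rate probability that a gene is annotated with any
#'   given leaf term.
#' @param n_carriers genes carrying the planted enrichment term.
#' @param planted_term term id carrying the planted signal; `NULL` picks
#'   the first biological_process leaf.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_genomes = 3L,
                         proteins_per_genome = 20L,
                         n_ortholog_groups = 5L,
                         paralog_family_sizes = c(3L, 2L),
                         noise_hit_rate = 0.05,
                         depth = 4L, branching = 2L,
                         diamond_fraction = 0.1,
                         background_rate = 0.05,
                         n_carriers = 20L,
                         planted_term = NULL) {
  stopifnot(seed == as.integer(seed), n_genomes >= 1,
            proteins_per_genome >= 1, n_ortholog_groups >= 0,
            all(paralog_family_sizes >= 1) || !length(paralog_family_sizes),
            noise_hit_rate >= 0, depth >= 1, branching >= 1,
            diamond_fraction >= 0, diamond_fraction <= 1,
            background_rate >= 0, background_rate <= 1, n_carriers >= 0)
  if (n_ortholog_groups + sum(paralog_family_sizes) > proteins_per_genome)
    stop("planted structure needs more proteins than proteins_per_genome")
  structure(list(seed = as.integer(seed), n_genomes = n_genomes,
                 proteins_per_genome = proteins_per_genome,
                 n_ortholog_groups = n_ortholog_groups,
                 paralog_family_sizes = paralog_family_sizes,
                 noise_hit_rate = noise_hit_rate, depth = depth,
                 branching = branching, diamond_fraction = diamond_fraction,
                 background_rate = background_rate,
                 n_carriers = n_carriers, planted_term = planted_term),
            class = "fixture_spec")
}

#' Generate a toy three-namespace ontology
#'
#' Each namespace is a rooted `branching`-ary tree of the given depth
#' (depth 1 = root only), plus a seeded fraction of "diamond" nodes that
#' receive a second parent from the level above (relation drawn uniformly
#' from is_a / part_of).  Direct children of the roots are tagged with the
#' subset `goslim_synthetic`.  Deterministic per seed.
#'
#' @param spec a `fixture_spec`.
#' @return an `ontology_graph`.
#' @export
make_ontology <- function(spec) {
  with_local_seed(spec$seed, {
    ids <- character(); name <- character(); namespace <- character()
    parents <- list(); subsets <- list()
    counter <- 0L
    next_id <- function() {
      counter <<- counter + 1L
      sprintf("GO:%07d", counter)
    }
    for (ns in GO_NAMESPACES) {
      levels <- vector("list", spec$depth)
      root <- next_id()
      levels[[1]] <- root
      ids <- c(ids, root); name[root] <- paste(ns, "root")
      namespace[root] <- ns; parents[[root]] <- character()
      subsets[[root]] <- character()
      if (spec$depth >= 2) for (d in 2:spec$depth) {
        lvl <- character()
        for (par in levels[[d - 1]]) {
          for (b in seq_len(spec$branching)) {
            id <- next_id()
            lvl <- c(lvl, id)
            ids <- c(ids, id)
            name[id] <- sprintf("%s L%d %s.%d", ns, d, par, b)
            namespace[id] <- ns
            parents[[id]] <- structure("is_a", names = par)
            subsets[[id]] <- if (d == 2) "goslim_synthetic" else character()
          }
        }
        levels[[d]] <- lvl
        # diamonds: extra parent from the level above
        if (length(levels[[d - 1]]) >= 2 && spec$diamond_fraction > 0) {
          n_dia <- floor(spec$diamond_fraction * length(lvl))
          if (n_dia >= 1) for (id in sample(lvl, n_dia)) {
            cur_par <- names(parents[[id]])
            extra <- sample(setdiff(levels[[d - 1]], cur_par), 1L)
            rel <- sample(c("is_a", "part_of"), 1L)
            p <- parents[[id]]
            p[extra] <- rel
            parents[[id]] <- p
          }
        }
      }
    }
    g <- new_ontology_graph(ids, name, namespace,
                            obsolete = rep(FALSE, length(ids)),
                            parents = parents, subsets = subsets[ids])
    g
  })
}

#' Leaf terms of a namespace
#' @param graph an `ontology_graph`.
#' @param namespace one of the three GO namespaces, or `NULL` for all.
#' @return character vector of terms that are no term's parent.
#' @export
leaf_terms <- function(graph, namespace = NULL) {
  edges <- ontology_edges(graph)
  leaves <- setdiff(graph$ids[!graph$obsolete], edges$parent)
  if (!is.null(namespace))
    leaves <- leaves[graph$namespace[leaves] == namespace]
  sort(leaves)
}

#' Generate proteomes and an all-vs-all hit table with planted structure
#'
#' Planted ortholog groups (one member per genome) receive reciprocal
#' top-bitscore cross-genome hits whose scores strictly dominate all noise
#' by a fixed margin; planted paralog families receive complete intra-genome
#' hit graphs with identity >= 80, so family members share match
#' neighbourhoods (pairwise J = 1 at zero noise).  Noise hits are random
#' pairs with identity below 80 (intra-genome) or bitscores below the
#' planted margin (cross-genome).
#'
#' @param spec a `fixture_spec`.
#' @return list with `proteomes` (data.frame `genome`, `protein`), `hits`
#'   (12-column data.frame) and `truth` (planted `ortholog_groups` and
#'   `paralog_families` data.frames).
#' @export
make_proteomes_hits <- function(spec) {
  with_local_seed(spec$seed + 1L, {
    genomes <- sprintf("g%02d", seq_len(spec$n_genomes))
    proteomes <- do.call(rbind, lapply(genomes, function(g) {
      data.frame(genome = g,
                 protein = sprintf("%s_p%03d", g,
                                   seq_len(spec$proteins_per_genome)),
                 stringsAsFactors = FALSE)
    }))
    prot <- function(g, i) sprintf("%s_p%03d", g, i)
    hit <- function(q, s, pident, evalue, bitscore) {
      data.frame(qseqid = q, sseqid = s, pident = pident, length = 200L,
                 mismatch = 10L, gapopen = 1L, qstart = 1L, qend = 200L,
                 sstart = 1L, send = 200L, evalue = evalue,
                 bitscore = bitscore, stringsAsFactors = FALSE)
    }
    hits <- list()
    truth_og <- NULL
    # ortholog groups occupy protein indices 1..n_ortholog_groups
    if (spec$n_ortholog_groups >= 1 && spec$n_genomes >= 2) {
      for (o in seq_len(spec$n_ortholog_groups)) {
        members <- prot(genomes, o)
        truth_og <- rbind(truth_og,
                          data.frame(group = o, genome = genomes,
                                     protein = members,
                                     stringsAsFactors = FALSE))
        for (i in seq_along(members)) for (j in seq_along(members)) {
          if (i != j)
            hits[[length(hits) + 1L]] <-
              hit(members[i], members[j], 90 + o %% 10, 1e-50,
                  900 + o)   # unique high score per group, no ties
        }
      }
    }
    # paralog families occupy the next indices in every genome
    truth_pf <- NULL
    fam_sizes <- spec$paralog_family_sizes
    if (length(fam_sizes)) {
      for (g in genomes) {
        idx <- spec$n_ortholog_groups
        for (f in seq_along(fam_sizes)) {
          members <- prot(g, idx + seq_len(fam_sizes[f]))
          idx <- idx + fam_sizes[f]
          truth_pf <- rbind(truth_pf,
                            data.frame(genome = g, family = f,
                                       protein = members,
                                       stringsAsFactors = FALSE))
          if (length(members) >= 2)
            for (i in seq_along(members)) for (j in seq_along(members)) {
              if (i != j)
                hits[[length(hits) + 1L]] <-
                  hit(members[i], members[j], 85 + f, 1e-30, 600 + f)
            }
        }
      }
    }
    # noise: random pairs, never competitive with planted structure
    n_noise <- round(spec$noise_hit_rate * nrow(proteomes))
    if (n_noise >= 1) {
      for (z in seq_len(n_noise)) {
        qs <- sample(proteomes$protein, 2L)
        same <- proteomes$genome[match(qs[1], proteomes$protein)] ==
          proteomes$genome[match(qs[2], proteomes$protein)]
        if (same) {
          hits[[length(hits) + 1L]] <-
            hit(qs[1], qs[2], stats::runif(1, 30, 79), 1e-6,
                stats::runif(1, 50, 200))
        } else {
          hits[[length(hits) + 1L]] <-
            hit(qs[1], qs[2], stats::runif(1, 30, 79), 1e-6,
                stats::runif(1, 50, 400))   # below the planted 600+ margin
        }
      }
    }
    hits <- if (length(hits)) do.call(rbind, hits) else
      data.frame(qseqid = character(), sseqid = character(),
                 pident = numeric(), length = integer(),
                 mismatch = integer(), gapopen = integer(),
                 qstart = integer(), qend = integer(), sstart = integer(),
                 send = integer(), evalue = numeric(),
                 bitscore = numeric(), stringsAsFactors = FALSE)
    rownames(hits) <- NULL
    list(proteomes = proteomes, hits = hits,
         truth = list(ortholog_groups = truth_og,
                      paralog_families = truth_pf))
  })
}

#' Generate an annotation table with planted enrichment signal
#'
#' Every gene receives each leaf term of the ontology independently with
#' probability `background_rate`; the planted term is additionally assigned
#' to a seeded random subset of `n_carriers` genes, creating a known
#' over-representation effect for those carriers.
#'
#' @param spec a `fixture_spec`.
#' @param graph an `ontology_graph` from [make_ontology()].
#' @param genes character vector of gene ids to annotate.
#' @return an `annotation_table` (evidence `IEA`) with attributes
#'   `planted_term` and `carriers`.
#' @export
make_annotation <- function(spec, graph, genes) {
  with_local_seed(spec$seed + 2L, {
    leaves <- leaf_terms(graph)
    planted <- spec$planted_term %||%
      leaf_terms(graph, "biological_process")[1]
    rec <- NULL
    if (spec$background_rate > 0 && length(leaves)) {
      pick <- stats::runif(length(genes) * length(leaves)) <
        spec$background_rate
      idx <- which(pick)
      rec <- data.frame(
        gene = genes[((idx - 1L) %% length(genes)) + 1L],
        term = leaves[((idx - 1L) %/% length(genes)) + 1L],
        stringsAsFactors = FALSE)
    }
    carriers <- character()
    if (spec$n_carriers > 0) {
      carriers <- sort(sample(genes, min(spec$n_carriers, length(genes))))
      rec <- rbind(rec, data.frame(gene = carriers, term = planted,
                                   stringsAsFactors = FALSE))
    }
    if (is.null(rec))
      rec <- data.frame(gene = character(), term = character(),
                        stringsAsFactors = FALSE)
    rec$evidence <- rep("IEA", nrow(rec))
    out <- annotation_table(rec, genome_id = "synthetic",
                            source = "synthetic fixture")
    attr(out, "planted_term") <- planted
    attr(out, "carriers") <- carriers
    out
  })
}

#' Reference mapping table fixture (printed per-genome counts)
#'
#' The ten published per-strain rows used by the mapping summary: predicted
#' transcripts, GO-annotated transcripts and distinct propagated GO term
#' counts for the reference (*A. nidulans*) and nine mapped target strains,
#' plus the count of reference transcripts that are both GO annotated and
#' member of an ortholog cluster (the mappable intersection, 3,405) and the
#' reference's propagated namespace composition.
#'
#' @return list with `rows` (data.frame `genome`, `strain`, `predicted`,
#'   `annotated`, `terms`), `reference_genome`, `intersection` and
#'   `namespace_counts` (BP/MF/CC term counts of the reference).
#' @export
table1_fixture <- function() {
  rows <- data.frame(
    genome = c("A. nidulans", "A. fumigatus", "A. fumigatus.A1163",
               "A. flavus", "A. niger.CBS513.88", "A. niger.ATCC1015",
               "A. oryzae", "A. terreus", "A. clavatus", "N. fischeri"),
    strain = c("FGSC A4", "AF2937", "A1163", "NRRL 3357", "CBS 513.88",
               "ATCC 1015", "RIB40", "NIH 2624", "NRRL 1", "NRRL 181"),
    predicted = c(10546L, 9846L, 10109L, 13487L, 14366L, 11200L, 12319L,
                  10402L, 9379L, 10728L),
    annotated = c(3498L, 3443L, 3450L, 3574L, 3540L, 3487L, 3502L, 3414L,
                  3403L, 3543L),
    terms = c(5508L, 5445L, 5446L, 5463L, 5430L, 5412L, 5434L, 5406L,
              5449L, 5445L),
    stringsAsFactors = FALSE)
  list(rows = rows,
       reference_genome = "A. nidulans",
       intersection = 3405L,
       namespace_counts = c(biological_process = 3061L,
                            molecular_function = 1753L,
                            cellular_component = 694L))
}

#' Write an ontology graph as OBO 1.2 text
#'
#' Emits one `[Term]` stanza per term (sorted by id) with id, name,
#' namespace, alt_id, subset, is_a / relationship and is_obsolete tags, so
#' synthetic ontologies can round-trip through [parse_obo()].
#'
#' @param graph an `ontology_graph`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_obo <- function(graph, path) {
  out <- c("format-version: 1.2", "ontology: synthetic")
  for (id in sort(graph$ids)) {
    stanza <- c("", "[Term]",
                paste0("id: ", id),
                paste0("name: ", graph$name[id]),
                paste0("namespace: ", graph$namespace[id]))
    alts <- names(graph$alt)[graph$alt == id]
    for (a in sort(alts)) stanza <- c(stanza, paste0("alt_id: ", a))
    for (s in sort(graph$subsets[[id]]))
      stanza <- c(stanza, paste0("subset: ", s))
    p <- graph$parents[[id]]
    for (par in sort(names(p))) {
      stanza <- c(stanza,
                  if (p[[par]] == "is_a") paste0("is_a: ", par)
                  else paste0("relationship: ", p[[par]], " ", par))
    }
    if (graph$obsolete[id]) stanza <- c(stanza, "is_obsolete: true")
    out <- c(out, stanza)
  }
  writeLines(out, path)
  invisible(path)
}
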