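# Two-step ortholog detection: within-genome Jaccard clustering of BLASTP
# match sets, then cross-genome linking of clusters by reciprocal best hits.

#' Clustering parameters
#'
#' Defaults follow the published two-step clustering procedure: hits are
#' kept at
#' E-value <= 1e-5; the within-genome (paralog) stage additionally requires
#' at least 80% sequence identity; a pair of proteins is connected iff its
#' match-set Jaccard coefficient strictly exceeds 0.6.
#'
#' @param max_evalue maximum E-value for any hit (inclusive).
#' @param min_identity minimum percent identity for the paralog stage
#'   (inclusive).
#' @param jaccard_threshold proteins are connected iff J strictly exceeds
#'   this value.
#' @return a `clustering_params` list.
#' @export
clustering_params <- function(max_evalue = 1e-5, min_identity = 80,
                              jaccard_threshold = 0.6) {
  stopifnot(max_evalue >= 0, min_identity >= 0, min_identity <= 100,
            jaccard_threshold >= 0, jaccard_threshold <= 1)
  structure(list(max_evalue = max_evalue, min_identity = min_identity,
                 jaccard_threshold = jaccard_threshold),
            class = "clustering_params")
}

BLAST_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Read 12-column tabular protein similarity hits
#'
#' Standard BLAST outfmt-6 style columns: qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore.
#' @param path tab-separated file, no header.
#' @return data.frame of hits.
#' @export
read_blast_tab <- function(path) {
  if (!length(readLines(path, n = 1L, warn = FALSE)))
    return(data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      mismatch = integer(), gapopen = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  hits <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(hits) != 12L)
    stop("expected 12 tab-separated columns in ", path, ", found ",
         ncol(hits))
  names(hits) <- BLAST_COLUMNS
  hits
}

#' Write hits in 12-column tabular format
#' @param hits data.frame with the 12 standard columns.
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  stopifnot(all(BLAST_COLUMNS %in% names(hits)))
  utils::write.table(hits[, BLAST_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a proteome roster (FASTA ids or a plain id list)
#'
#' Only identifiers are used: for FASTA the first whitespace-separated token
#' of each header; for a plain list one id per line (`#` comments allowed).
#'
#' @param path input file.
#' @param genome genome label.
#' @param format `"auto"` (sniff a leading `>`), `"fasta"` or `"ids"`.
#' @return data.frame with columns `genome`, `protein`.
#' @export
read_proteome <- function(path, genome, format = c("auto", "fasta", "ids")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) && startsWith(first, ">")) "fasta" else "ids"
  }
  ids <- if (format == "fasta") {
    headers <- names(Biostrings::readAAStringSet(path))
    vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  } else {
    lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
    lines[nzchar(lines)]
  }
  if (anyDuplicated(ids))
    stop("duplicate protein id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(genome = genome, protein = ids, stringsAsFactors = FALSE)
}

#' Write a proteome id list
#' @param proteome data.frame with columns `genome`, `protein` (one genome).
#' @param path output path.
#' @export
write_proteome <- function(proteome, path) {
  writeLines(proteome$protein, path)
  invisible(path)
}

genome_lookup <- function(proteomes) {
  if (anyDuplicated(proteomes$protein))
    stop("protein ids must be unique across genomes: ",
         paste(unique(proteomes$protein[duplicated(proteomes$protein)]),
               collapse = ", "))
  structure(proteomes$genome, names = proteomes$protein)
}

#' Filter similarity hits for a clustering stage
#'
#' The paralog stage keeps same-genome, non-self hits with E-value <=
#' `max_evalue` and identity >= `min_identity` (both boundaries inclusive).
#' The ortholog stage keeps cross-genome hits with E-value <= `max_evalue`
#' only.  When several hits exist for one (query, subject) pair, the
#' maximal-bitscore one is kept.
#'
#' @param hits data.frame of 12-column hits.
#' @param proteomes data.frame with columns `genome`, `protein`; every hit
#'   must reference a known protein.
#' @param params a `clustering_params`.
#' @param stage `"paralog"` or `"ortholog"`.
#' @return filtered data.frame of hits.
#' @export
filter_hits <- function(hits, proteomes, params = clustering_params(),
                        stage = c("paralog", "ortholog")) {
  stage <- match.arg(stage)
  gmap <- genome_lookup(proteomes)
  unknown <- setdiff(unique(c(hits$qseqid, hits$sseqid)), names(gmap))
  if (length(unknown))
    stop("hit references unknown protein: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  qg <- gmap[hits$qseqid]
  sg <- gmap[hits$sseqid]
  keep <- hits$evalue <= params$max_evalue
  if (stage == "paralog") {
    keep <- keep & qg == sg & hits$qseqid != hits$sseqid &
      hits$pident >= params$min_identity
  } else {
    keep <- keep & qg != sg
  }
  out <- hits[keep, , drop = FALSE]
  # keep the best-scoring hit per (query, subject) pair
  out <- out[order(-out$bitscore, out$qseqid, out$sseqid), , drop = FALSE]
  out <- out[!duplicated(paste(out$qseqid, out$sseqid)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Within-genome BLASTP match sets
#'
#' The match set of a protein P is P itself, plus the same-genome subjects
#' of P's kept hits, plus the same-genome queries hitting P; it is symmetric
#' over hit direction by construction.
#'
#' @param proteins character vector of one genome's protein ids.
#' @param hits paralog-stage filtered hits for that genome.
#' @return named list protein -> sorted character vector (the match set).
#' @export
match_sets <- function(proteins, hits) {
  hits <- hits[hits$qseqid %in% proteins & hits$sseqid %in% proteins, ,
               drop = FALSE]
  adj_from <- c(hits$qseqid, hits$sseqid)
  adj_to <- c(hits$sseqid, hits$qseqid)
  spl <- split(adj_to, factor(adj_from, levels = proteins))
  out <- lapply(seq_along(proteins), function(i) {
    sort(unique(c(proteins[i], spl[[i]])))
  })
  names(out) <- proteins
  out
}

#' Jaccard coefficient of two match sets
#'
#' `|m1 n m2| / |m1 u m2|`; 0 when the union is empty.
#' @param m1,m2 character vectors (match sets from the same genome).
#' @return number in [0, 1].
#' @export
jaccard_coefficient <- function(m1, m2) {
  u <- union(m1, m2)
  if (!length(u)) return(0)
  length(intersect(m1, m2)) / length(u)
}

# Edges of the within-genome Jaccard graph: pairs with J > threshold.
# Candidate pairs are restricted to proteins whose match sets intersect
# (a positive J requires a shared match), found via an inverted index.
jaccard_edges <- function(msets, threshold) {
  inv <- list()
  for (p in names(msets)) {
    for (x in msets[[p]]) inv[[x]] <- c(inv[[x]], p)
  }
  pairs <- unique(do.call(rbind, lapply(inv, function(bucket) {
    if (length(bucket) < 2L) return(NULL)
    t(utils::combn(sort(bucket), 2L))
  })))
  if (is.null(pairs) || !nrow(pairs))
    return(data.frame(a = character(), b = character()))
  j <- vapply(seq_len(nrow(pairs)), function(i) {
    jaccard_coefficient(msets[[pairs[i, 1]]], msets[[pairs[i, 2]]])
  }, numeric(1))
  data.frame(a = pairs[j > threshold, 1], b = pairs[j > threshold, 2],
             stringsAsFactors = FALSE)
}

#' Build within-genome Jaccard clusters (paralog families)
#'
#' Connects two proteins of a genome iff the Jaccard coefficient of their
#' match sets strictly exceeds `params$jaccard_threshold`; the connected
#' components of this graph are the Jaccard clusters.  Every protein lands
#' in exactly one cluster (singletons allowed).
#'
#' @param hits raw similarity hits (the paralog-stage filter is applied
#'   internally).
#' @param proteomes data.frame `genome`, `protein`.
#' @param params a `clustering_params`.
#' @param genome optional single genome label; default all genomes.
#' @return data.frame with columns `cluster_id`, `genome`, `protein`.
#' @export
build_jaccard_clusters <- function(hits, proteomes,
                                   params = clustering_params(),
                                   genome = NULL) {
  fhits <- filter_hits(hits, proteomes, params, stage = "paralog")
  genomes <- if (is.null(genome)) sort(unique(proteomes$genome)) else genome
  out <- lapply(genomes, function(g) {
    prot <- proteomes$protein[proteomes$genome == g]
    msets <- match_sets(prot, fhits)
    edges <- jaccard_edges(msets, params$jaccard_threshold)
    ig <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                        vertices = data.frame(name = prot))
    comp <- igraph::components(ig)$membership
    # deterministic ids: clusters numbered by their smallest member
    k <- if (length(comp)) max(comp) else 0L
    first <- vapply(seq_len(k), function(ci) min(names(comp)[comp == ci]),
                    character(1))
    cluster_rank <- order(order(first))
    data.frame(
      cluster_id = sprintf("%s.JC%04d", g, cluster_rank[comp]),
      genome = g, protein = names(comp), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$cluster_id, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- params
  out
}

#' Best cross-genome hits of a Jaccard cluster
#'
#' For each member of the cluster, its maximal-bitscore subject in the
#' target genome (all tied subjects retained); the union over members is
#' returned.
#'
#' @param members character vector of the cluster's protein ids.
#' @param genome_b target genome label.
#' @param hits ortholog-stage filtered hits.
#' @param proteomes data.frame `genome`, `protein`.
#' @return character vector of protein ids in `genome_b`.
#' @export
best_hits <- function(members, genome_b, hits, proteomes) {
  gmap <- genome_lookup(proteomes)
  h <- hits[hits$qseqid %in% members & gmap[hits$sseqid] == genome_b, ,
            drop = FALSE]
  if (!nrow(h)) return(character())
  mx <- tapply(h$bitscore, h$qseqid, max)
  sort(unique(h$sseqid[h$bitscore == mx[h$qseqid]]))
}

#' Reciprocal-best-hit edges between Jaccard clusters
#'
#' Clusters A (genome GA) and B (genome GB != GA) are connected iff some
#' member of A has its best hit in GB inside B, and some member of B has
#' its best hit in GA inside A (cluster-level reciprocal best hits).
#'
#' @param jclusters data.frame from [build_jaccard_clusters()].
#' @param hits ortholog-stage filtered hits (see [filter_hits()]).
#' @param proteomes data.frame `genome`, `protein`.
#' @return data.frame of unordered cluster-id pairs (`a` < `b`).
#' @export
rbh_cluster_edges <- function(jclusters, hits, proteomes) {
  empty <- data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  gmap <- genome_lookup(proteomes)
  cmap <- structure(jclusters$cluster_id, names = jclusters$protein)
  tg <- unname(gmap[hits$sseqid])
  # per (query, target genome): maximal-bitscore subjects, ties retained
  key <- paste(hits$qseqid, tg)
  mx <- tapply(hits$bitscore, key, max)
  best <- hits[hits$bitscore == mx[key], , drop = FALSE]
  reach <- unique(data.frame(from = unname(cmap[best$qseqid]),
                             to = unname(cmap[best$sseqid]),
                             stringsAsFactors = FALSE))
  fwd <- paste(reach$from, reach$to)
  rev <- paste(reach$to, reach$from)
  mutual <- reach[fwd %in% rev, , drop = FALSE]
  if (!nrow(mutual)) return(empty)
  a <- pmin(mutual$from, mutual$to)
  b <- pmax(mutual$from, mutual$to)
  out <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble Jaccard orthologous clusters
#'
#' Connected components of the cluster-level reciprocal-best-hit graph.
#' Components spanning at least two Jaccard clusters become ortholog
#' clusters; isolated clusters are reported as unclustered.
#'
#' @param jclusters data.frame from [build_jaccard_clusters()].
#' @param edges data.frame from [rbh_cluster_edges()].
#' @return an `ortholog_clusters` object: `$clusters` (data.frame
#'   `ortholog_id`, `jaccard_id`, `genome`, `protein`), `$unclustered`
#'   (isolated Jaccard cluster ids) and `$edges`.
#' @export
build_ortholog_clusters <- function(jclusters, edges) {
  cl_ids <- sort(unique(jclusters$cluster_id))
  ig <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                      vertices = data.frame(name = cl_ids))
  comp <- igraph::components(ig)$membership
  sizes <- table(comp)
  in_oc <- comp[sizes[as.character(comp)] >= 2L]
  unclustered <- sort(setdiff(cl_ids, names(in_oc)))
  if (length(in_oc)) {
    comps <- sort(unique(as.integer(in_oc)))
    first <- vapply(comps, function(ci) min(names(in_oc)[in_oc == ci]),
                    character(1))
    comp_rank <- order(order(first))       # rank of each component
    oc_id <- sprintf("OC%05d", comp_rank[match(as.integer(in_oc), comps)])
    names(oc_id) <- names(in_oc)
    keep <- jclusters$cluster_id %in% names(in_oc)
    clusters <- data.frame(
      ortholog_id = unname(oc_id[jclusters$cluster_id[keep]]),
      jaccard_id = jclusters$cluster_id[keep],
      genome = jclusters$genome[keep],
      protein = jclusters$protein[keep], stringsAsFactors = FALSE)
    clusters <- clusters[order(clusters$ortholog_id, clusters$jaccard_id,
                               clusters$protein), , drop = FALSE]
    rownames(clusters) <- NULL
  } else {
    clusters <- data.frame(ortholog_id = character(),
                           jaccard_id = character(), genome = character(),
                           protein = character(), stringsAsFactors = FALSE)
  }
  structure(list(clusters = clusters, unclustered = unclustered,
                 edges = edges),
            class = "ortholog_clusters")
}

#' @export
print.ortholog_clusters <- function(x, ...) {
  cat("ortholog_clusters:", length(unique(x$clusters$ortholog_id)),
      "clusters over", nrow(x$clusters), "proteins;",
      length(x$unclustered), "unclustered Jaccard clusters\n")
  invisible(x)
}

#' Round a ratio to a whole percentage
#'
#' The rounding convention used by every summary in the package:
#' `round(100 * part / whole)` (0 when `whole` is 0).
#' @param part,whole non-negative numbers.
#' @return integer percentage.
#' @export
percent_rounded <- function(part, whole) {
  whole <- rep_len(whole, length(part))
  as.integer(ifelse(whole > 0, round(100 * part / whole), 0))
}

#' Summarise a clustering
#'
#' Per-genome and total protein counts, how many proteins sit inside
#' ortholog clusters, the fraction clustered (rounded to the nearest whole
#' percent) and the number of ortholog clusters.
#'
#' @param oclusters an `ortholog_clusters` object.
#' @param proteomes data.frame `genome`, `protein`.
#' @return a `clustering_summary`: data.frame with columns `genome`,
#'   `proteins`, `clustered`, `percent` (a `total` row last); attribute
#'   `n_clusters`.
#' @export
clustering_summary <- function(oclusters, proteomes) {
  genomes <- sort(unique(proteomes$genome))
  clustered_prot <- oclusters$clusters$protein
  rows <- do.call(rbind, lapply(genomes, function(g) {
    prot <- proteomes$protein[proteomes$genome == g]
    ncl <- sum(prot %in% clustered_prot)
    data.frame(genome = g, proteins = length(prot), clustered = ncl,
               percent = percent_rounded(ncl, length(prot)),
               stringsAsFactors = FALSE)
  }))
  total <- data.frame(genome = "total", proteins = nrow(proteomes),
                      clustered = length(clustered_prot),
                      percent = percent_rounded(length(clustered_prot),
                                                nrow(proteomes)),
                      stringsAsFactors = FALSE)
  out <- rbind(rows, total)
  rownames(out) <- NULL
  attr(out, "n_clusters") <- length(unique(oclusters$clusters$ortholog_id))
  class(out) <- c("clustering_summary", "data.frame")
  out
}

#' @export
print.clustering_summary <- function(x, ...) {
  cat("clustering_summary (", attr(x, "n_clusters"),
      " ortholog clusters):\n", sep = "")
  print.data.frame(x)
  invisible(x)
}

#' Run the full two-step clustering
#'
#' Paralog-stage filtering + Jaccard clustering per genome, ortholog-stage
#' filtering + cluster-level reciprocal best hits across genomes, connected
#' components, and a summary.
#'
#' @param hits raw 12-column similarity hits.
#' @param proteomes data.frame `genome`, `protein`.
#' @param params a `clustering_params`.
#' @return list with `jaccard` (data.frame), `edges`, `ortholog`
#'   (`ortholog_clusters`), `summary` (`clustering_summary`) and `params`.
#' @export
cluster_proteomes <- function(hits, proteomes, params = clustering_params()) {
  jc <- build_jaccard_clusters(hits, proteomes, params)
  ohits <- filter_hits(hits, proteomes, params, stage = "ortholog")
  edges <- rbh_cluster_edges(jc, ohits, proteomes)
  oc <- build_ortholog_clusters(jc, edges)
  list(jaccard = jc, edges = edges, ortholog = oc,
       summary = clustering_summary(oc, proteomes), params = params)
}

#' Write clusters as TSV (cluster_id, genome, protein)
#' @param clusters data.frame of Jaccard clusters, or an
#'   `ortholog_clusters` object (written with its `ortholog_id` and
#'   `jaccard_id` columns).
#' @param path output path.
#' @export
write_clusters <- function(clusters, path) {
  df <- if (inherits(clusters, "ortholog_clusters")) clusters$clusters
        else clusters
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a cluster TSV written by [write_clusters()]
#' @param path input path.
#' @return data.frame; an `ortholog_clusters`-shaped table if it has an
#'   `ortholog_id` column.
#' @export
read_clusters <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("ortholog_id" %in% names(df)) {
    structure(list(clusters = df, unclustered = character(),
                   edges = NULL),
              class = "ortholog_clusters")
  } else df
}
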