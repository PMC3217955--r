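# Independent brute-force oracles and small fixture builders used across
# the suite.  Everything here is deliberately naive (loops, enumeration,
# union-find) and shares no code with the package implementation.

# ---- toy ontologies ---------------------------------------------------

# Build an ontology from a parent specification and parse it through the
# public OBO surface.  parents: named list id -> named character vector
# (names = parent ids, values = relation).
toy_ontology <- function(parents, namespace = "biological_process",
                         obsolete = character(), alt = character()) {
  ids <- names(parents)
  lines <- c("format-version: 1.2")
  for (id in ids) {
    lines <- c(lines, "", "[Term]", paste0("id: ", id),
               paste0("name: name of ", id),
               paste0("namespace: ",
                      if (length(namespace) > 1) namespace[[id]]
                      else namespace))
    for (a in names(alt)[alt == id])
      lines <- c(lines, paste0("alt_id: ", a))
    p <- parents[[id]]
    for (par in names(p)) {
      lines <- c(lines,
                 if (p[[par]] == "is_a") paste0("is_a: ", par)
                 else paste0("relationship: ", p[[par]], " ", par))
    }
    if (id %in% obsolete) lines <- c(lines, "is_obsolete: true")
  }
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  parse_obo(path)
}

go_id <- function(i) sprintf("GO:%07d", i)

# Random single-rooted DAG over n nodes (node 1 is the root); every other
# node picks 1-2 parents among lower-numbered nodes.
random_dag_ontology <- function(n) {
  parents <- list()
  parents[[go_id(1)]] <- character()
  if (n >= 2) for (i in 2:n) {
    np <- sample(1:min(2L, i - 1L), 1L)
    ps <- sample(seq_len(i - 1L), np)
    rel <- sample(c("is_a", "part_of"), np, replace = TRUE)
    parents[[go_id(i)]] <- structure(rel, names = go_id(ps))
  }
  toy_ontology(parents)
}

# Exhaustive DFS path enumeration of ancestors (excluding self).
oracle_ancestors <- function(graph, id, relations = GO_RELATIONS) {
  found <- character()
  walk <- function(x) {
    p <- graph$parents[[x]]
    up <- names(p)[p %in% relations]
    for (q in up) {
      found <<- c(found, q)
      walk(q)
    }
  }
  walk(id)
  sort(unique(found))
}

# ---- hypergeometric tail by enumeration -------------------------------

oracle_hyper_tail <- function(k, n, K, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i) {
    choose(K, i) * choose(N - K, n - i)
  }, numeric(1))) / choose(N, n)
}

# ---- naive two-step clustering oracle ---------------------------------

# Plain union-find with path halving.
uf_make <- function(items) {
  e <- new.env(parent = emptyenv())
  for (x in items) assign(x, x, envir = e)
  e
}
uf_find <- function(e, x) {
  while (get(x, envir = e) != x) {
    gp <- get(get(x, envir = e), envir = e)
    assign(x, gp, envir = e)
    x <- gp
  }
  x
}
uf_union <- function(e, x, y) {
  assign(uf_find(e, x), uf_find(e, y), envir = e)
}
uf_groups <- function(e, items) {
  roots <- vapply(items, function(x) uf_find(e, x), character(1))
  unname(lapply(split(items, roots), sort))
}

canonical_partition <- function(groups) {
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, `[[`, character(1), 1L))]
}

# End-to-end naive reimplementation of the two-step clustering: explicit
# loops, all-pairs Jaccard, union-find components.  Returns the Jaccard
# partition per genome and the ortholog clusters as protein-set partitions.
oracle_two_step <- function(hits, proteomes, params) {
  gmap <- structure(proteomes$genome, names = proteomes$protein)
  dedupe_best <- function(h) {
    if (!nrow(h)) return(h)
    keep <- rep(TRUE, nrow(h))
    key <- paste(h$qseqid, h$sseqid)
    for (kk in unique(key)) {
      idx <- which(key == kk)
      best <- idx[which.max(h$bitscore[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
    h[keep, , drop = FALSE]
  }
  par_hits <- hits[hits$evalue <= params$max_evalue &
                     hits$pident >= params$min_identity &
                     hits$qseqid != hits$sseqid &
                     gmap[hits$qseqid] == gmap[hits$sseqid], , drop = FALSE]
  par_hits <- dedupe_best(par_hits)
  orth_hits <- hits[hits$evalue <= params$max_evalue &
                      gmap[hits$qseqid] != gmap[hits$sseqid], ,
                    drop = FALSE]
  orth_hits <- dedupe_best(orth_hits)

  jaccard_partition <- list()
  cluster_of <- character()
  n_cl <- 0L
  for (g in sort(unique(proteomes$genome))) {
    prot <- sort(proteomes$protein[proteomes$genome == g])
    msets <- list()
    for (p in prot) {
      m <- p
      for (r in seq_len(nrow(par_hits))) {
        if (par_hits$qseqid[r] == p) m <- c(m, par_hits$sseqid[r])
        if (par_hits$sseqid[r] == p) m <- c(m, par_hits$qseqid[r])
      }
      msets[[p]] <- sort(unique(m))
    }
    uf <- uf_make(prot)
    if (length(prot) >= 2) {
      for (i in 1:(length(prot) - 1)) for (j in (i + 1):length(prot)) {
        a <- msets[[prot[i]]]; b <- msets[[prot[j]]]
        jc <- length(intersect(a, b)) / length(union(a, b))
        if (jc > params$jaccard_threshold) uf_union(uf, prot[i], prot[j])
      }
    }
    groups <- uf_groups(uf, prot)
    jaccard_partition[[g]] <- canonical_partition(groups)
    for (grp in groups) {
      n_cl <- n_cl + 1L
      cluster_of[grp] <- paste0("cl", n_cl)
    }
  }

  # cluster-level best hits and reciprocal edges, by loops
  clusters <- split(names(cluster_of), cluster_of)
  cl_genome <- vapply(clusters, function(m) unname(gmap[m[1]]),
                      character(1))
  best_of <- function(members, gb) {
    out <- character()
    for (p in members) {
      rows <- which(orth_hits$qseqid == p & gmap[orth_hits$sseqid] == gb)
      if (!length(rows)) next
      mx <- max(orth_hits$bitscore[rows])
      out <- c(out, orth_hits$sseqid[rows][orth_hits$bitscore[rows] == mx])
    }
    unique(out)
  }
  ids <- names(clusters)
  uf2 <- uf_make(ids)
  if (length(ids) >= 2) {
    for (i in 1:(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      a <- ids[i]; b <- ids[j]
      if (cl_genome[a] == cl_genome[b]) next
      ab <- length(intersect(best_of(clusters[[a]], cl_genome[b]),
                             clusters[[b]])) > 0
      ba <- length(intersect(best_of(clusters[[b]], cl_genome[a]),
                             clusters[[a]])) > 0
      if (ab && ba) uf_union(uf2, a, b)
    }
  }
  comp <- uf_groups(uf2, ids)
  oc <- Filter(function(cc) length(cc) >= 2, comp)
  oc_prot <- lapply(oc, function(cc) sort(unlist(clusters[cc],
                                                 use.names = FALSE)))
  list(jaccard = jaccard_partition,
       ortholog = canonical_partition(oc_prot))
}

# Random similarity-hit instance for the clustering oracle comparisons.
random_cluster_instance <- function() {
  n_genomes <- sample(2:4, 1)
  proteomes <- do.call(rbind, lapply(seq_len(n_genomes), function(gi) {
    n <- sample(3:15, 1)
    data.frame(genome = paste0("g", gi),
               protein = sprintf("g%d_p%02d", gi, seq_len(n)),
               stringsAsFactors = FALSE)
  }))
  n_hits <- sample(10:60, 1)
  idx_q <- sample(nrow(proteomes), n_hits, replace = TRUE)
  idx_s <- sample(nrow(proteomes), n_hits, replace = TRUE)
  hits <- data.frame(
    qseqid = proteomes$protein[idx_q],
    sseqid = proteomes$protein[idx_s],
    pident = round(runif(n_hits, 50, 100), 1),
    length = 100L, mismatch = 5L, gapopen = 1L,
    qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
    evalue = 10^runif(n_hits, -12, -3),   # some above the 1e-5 cutoff
    bitscore = round(runif(n_hits, 50, 900), 1),
    stringsAsFactors = FALSE)
  list(proteomes = proteomes, hits = hits)
}

package_jaccard_partition <- function(jc) {
  lapply(split(jc, jc$genome), function(df) {
    canonical_partition(unname(lapply(split(df$protein, df$cluster_id),
                                      sort)))
  })
}

package_ortholog_partition <- function(oc) {
  canonical_partition(unname(lapply(
    split(oc$clusters$protein, oc$clusters$ortholog_id), sort)))
}
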