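# GO term enrichment: one-tailed Fisher's exact (hypergeometric) test,
# Benjamini-Hochberg FDR control, most-specific-term reduction, slim
# comparison matrices and result export.

#' Enrichment parameters
#'
#' @param alpha FDR significance threshold (a term is significant iff its
#'   q-value is <= `alpha`).
#' @param relations ontology relations traversed during propagation.
#' @param universe `"annotated_only"` (genes with at least one propagated
#'   term; default) or `"all_predicted"` (every protein of the proteome,
#'   annotated or not).
#' @param min_study_count candidate terms must be carried by at least this
#'   many study genes.
#' @param correction `"joint"` BH correction across all candidate terms of
#'   all namespaces (default), or `"per_namespace"`.
#' @return an `enrichment_params` list.
#' @export
enrichment_params <- function(alpha = 0.05, relations = GO_RELATIONS,
                              universe = c("annotated_only",
                                           "all_predicted"),
                              min_study_count = 1L,
                              correction = c("joint", "per_namespace")) {
  stopifnot(alpha > 0, alpha <= 1, min_study_count >= 1)
  structure(list(alpha = alpha, relations = relations,
                 universe = match.arg(universe),
                 min_study_count = as.integer(min_study_count),
                 correction = match.arg(correction)),
            class = "enrichment_params")
}

#' One-tailed Fisher's exact test for over-representation
#'
#' Upper tail of the hypergeometric distribution:
#' `p = sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) / C(N,n)` --
#' the probability of drawing at least `k` annotated genes when `n` genes
#' are sampled without replacement from a universe of `N` genes of which
#' `K` carry the term.
#'
#' @param k study genes carrying the term.
#' @param n study genes in the universe.
#' @param K universe genes carrying the term.
#' @param N universe size.
#' @return p-value(s) in (0, 1]; vectorised over `k` and `K`.
#' @export
one_tailed_fisher <- function(k, n, K, N) {
  if (any(k < 0) || any(n < 0) || any(K < 0) || any(N < 0) ||
      any(n > N) || any(K > N) || any(k > pmin(n, K)) ||
      any(k < pmax(0, n + K - N)))
    stop("invalid contingency counts: need 0 <= k <= min(n, K), ",
         "max(0, n + K - N) <= k, n <= N, K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' With ordered p-values `p_(1) <= ... <= p_(m)`, the adjusted value is
#' `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1, mapped back to the
#' input order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return q-values in input order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (any(pvalues < 0 | pvalues > 1 | is.na(pvalues)))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  q_sorted <- rev(cummin(rev(m * pvalues[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Read a study gene list
#' @param path plain-text file, one gene id per line; `#` starts a comment.
#' @return character vector of gene ids.
#' @export
read_study_genes <- function(path) {
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  unique(lines[nzchar(lines)])
}

#' GO term enrichment of a study gene set
#'
#' Propagates the background annotation (if not already propagated) and
#' tests each candidate term (carried by at least `min_study_count` study
#' genes) for over-representation with the one-tailed Fisher's exact test;
#' p-values are Benjamini-Hochberg corrected over the candidate family and
#' terms with q <= alpha are flagged significant.  Among the significant
#' terms, the most specific subset (no significant descendant) is marked.
#'
#' @param study_genes character vector of study gene ids; ids absent from
#'   the universe are tallied in the `unknown_ids` attribute, never
#'   silently dropped.
#' @param background an `annotation_table` of the universe's annotation.
#' @param graph an `ontology_graph`.
#' @param params an `enrichment_params`.
#' @param proteome optional data.frame `genome`, `protein`; required for
#'   the `all_predicted` universe policy.
#' @return an `enrichment_result` data.frame with columns `term`, `name`,
#'   `namespace`, `k`, `n`, `K`, `N`, `p`, `q`, `significant`,
#'   `most_specific`, ordered by q then p then term id.  Attributes:
#'   `universe_size`, `n_study`, `unknown_ids`, `params`.
#' @export
enrich <- function(study_genes, background, graph,
                   params = enrichment_params(), proteome = NULL) {
  if (!isTRUE(attr(background, "propagated")))
    background <- propagate(background, graph, params$relations)
  g2t <- gene_terms(background)
  universe <- if (params$universe == "annotated_only") {
    names(g2t)
  } else {
    if (is.null(proteome))
      stop("universe policy 'all_predicted' needs a proteome")
    unique(proteome$protein)
  }
  study_genes <- unique(study_genes)
  study <- intersect(study_genes, universe)
  unknown <- setdiff(study_genes, universe)
  if (!length(study))
    stop("no study gene maps to the universe (", length(unknown),
         " unknown id(s))")
  N <- length(universe)
  n <- length(study)
  K_tab <- table(unlist(g2t[intersect(universe, names(g2t))],
                        use.names = FALSE))
  k_tab <- table(unlist(g2t[intersect(study, names(g2t))],
                        use.names = FALSE))
  cand <- names(k_tab)[k_tab >= params$min_study_count]
  res <- data.frame(term = cand,
                    name = unname(graph$name[cand]),
                    namespace = unname(graph$namespace[cand]),
                    k = as.integer(k_tab[cand]),
                    n = n,
                    K = as.integer(K_tab[cand]),
                    N = N,
                    stringsAsFactors = FALSE)
  res$p <- if (nrow(res)) one_tailed_fisher(res$k, res$n, res$K, res$N)
           else numeric()
  res$q <- NA_real_
  if (nrow(res)) {
    if (params$correction == "joint") {
      res$q <- benjamini_hochberg(res$p)
    } else {
      for (ns in unique(res$namespace)) {
        i <- res$namespace == ns
        res$q[i] <- benjamini_hochberg(res$p[i])
      }
    }
  }
  res$significant <- res$q <= params$alpha
  res$most_specific <- FALSE
  if (any(res$significant)) {
    ms <- reduce_to_most_specific(res$term[res$significant], graph,
                                  params$relations)
    res$most_specific <- res$term %in% ms & res$significant
  }
  res <- res[order(res$q, res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  attr(res, "universe_size") <- N
  attr(res, "n_study") <- n
  attr(res, "unknown_ids") <- unknown
  attr(res, "params") <- params
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result: ", nrow(x), " candidate terms, ",
      sum(x$significant), " significant (",
      sum(x$most_specific), " most specific); study n = ",
      attr(x, "n_study"), ", universe N = ", attr(x, "universe_size"),
      "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Slim comparison matrix across enrichment result sets
#'
#' Maps each labelled set of (significant) enriched terms onto a GO slim by
#' single-occurrence counting and assembles the counts into a slim-term by
#' label matrix, the layout used to compare enrichment results across
#' species.
#'
#' @param sets named list label -> character vector of term ids (e.g.
#'   significant terms of an [enrich()] run per species).
#' @param slim a `slim_set`.
#' @param graph an `ontology_graph`.
#' @param relations relations to traverse.
#' @return integer matrix, rows = slim terms, columns = labels.
#' @export
slim_comparison <- function(sets, slim, graph, relations = GO_RELATIONS) {
  if (!length(sets)) stop("need at least one labelled term set")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("term sets must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate set label: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  cols <- lapply(sets, slim_count, slim = slim, graph = graph,
                 relations = relations)
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(sets)
  mat
}

#' Export enrichment results (TSV, text summary, DOT graphs)
#'
#' Writes `<prefix>_enrichment.tsv` (all candidate terms with counts and
#' statistics), `<prefix>_summary.txt` (a human-readable digest) and one
#' `<prefix>_<namespace>.dot` graph per namespace containing the
#' significant terms plus their ancestors up to the root; significant
#' nodes are filled.  The DOT files are valid input for standard SVG
#' renderers (`dot -Tsvg`).
#'
#' @param records an `enrichment_result`.
#' @param graph an `ontology_graph`.
#' @param out_prefix path prefix for the output files.
#' @param relations relations used for the ancestor closure in the graphs.
#' @return character vector of the written paths, invisibly.
#' @export
export_results <- function(records, graph, out_prefix,
                           relations = GO_RELATIONS) {
  tsv <- paste0(out_prefix, "_enrichment.tsv")
  ok <- try(utils::write.table(
    as.data.frame(records)[, c("term", "name", "namespace", "k", "n", "K",
                               "N", "p", "q", "significant",
                               "most_specific")],
    tsv, sep = "\t", quote = FALSE, row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write ", tsv)
  txt <- paste0(out_prefix, "_summary.txt")
  sig <- records[records$significant, , drop = FALSE]
  writeLines(c(
    sprintf("study genes in universe: %d of %d",
            attr(records, "n_study"), attr(records, "universe_size")),
    sprintf("unknown study ids: %d", length(attr(records, "unknown_ids"))),
    sprintf("candidate terms tested: %d", nrow(records)),
    sprintf("significant terms (q <= %g): %d",
            attr(records, "params")$alpha %||% NA, nrow(sig)),
    sprintf("most specific significant terms: %d",
            sum(records$most_specific)),
    "",
    sprintf("%s\t%s\t%.3g\t%s", sig$term, sig$namespace, sig$q, sig$name)),
    txt)
  paths <- c(tsv, txt)
  for (ns in GO_NAMESPACES) {
    dot <- paste0(out_prefix, "_", ns, ".dot")
    sig_ns <- sig$term[sig$namespace == ns]
    writeLines(dot_graph(sig_ns, graph, relations, name = ns), dot)
    paths <- c(paths, dot)
  }
  invisible(paths)
}

# DOT text for the sub-DAG induced by `terms` plus all their ancestors.
# Terms in `terms` are drawn filled; part_of edges are dashed.
dot_graph <- function(terms, graph, relations = GO_RELATIONS,
                      name = "GO") {
  header <- c(paste0("digraph \"", name, "\" {"),
              "  rankdir=BT;",
              "  node [shape=box, fontsize=10];")
  if (!length(terms)) return(c(header, "}"))
  clo <- term_closures(graph, terms, relations)
  nodes <- sort(unique(c(terms, unlist(clo, use.names = FALSE))))
  node_lines <- vapply(nodes, function(id) {
    label <- gsub("\"", "'", paste0(id, "\\n", graph$name[id]))
    style <- if (id %in% terms)
      ", style=filled, fillcolor=lightblue" else ""
    paste0("  \"", id, "\" [label=\"", label, "\"", style, "];")
  }, character(1))
  edges <- ontology_edges(graph)
  edges <- edges[edges$child %in% nodes & edges$parent %in% nodes &
                   edges$relation %in% relations, , drop = FALSE]
  edge_lines <- if (nrow(edges)) {
    style <- ifelse(edges$relation == "part_of", " [style=dashed]", "")
    paste0("  \"", edges$child, "\" -> \"", edges$parent, "\"", style, ";")
  } else character()
  c(header, node_lines, edge_lines, "}")
}
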