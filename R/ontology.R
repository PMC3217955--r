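# GO DAG handling: OBO parsing, ancestor closure, true-path propagation,
# most-specific reduction and GO-slim occurrence counting.

#' Relations traversed for ancestor closure
#'
#' The default closure follows `is_a` and `part_of` edges, the standard
#' true-path relations; regulates-type edges are never loaded.
#' @export
GO_RELATIONS <- c("is_a", "part_of")

GO_NAMESPACES <- c("biological_process", "molecular_function",
                   "cellular_component")

is_term_id <- function(x) grepl("^GO:[0-9]{7}$", x)

new_ontology_graph <- function(ids, name, namespace, obsolete, parents,
                               alt = character(), subsets = list()) {
  stopifnot(!anyDuplicated(ids))
  names(name) <- names(namespace) <- names(obsolete) <- ids
  parents <- parents[ids]
  names(parents) <- ids
  # canonical edge order, so structurally equal graphs compare identical
  parents <- lapply(parents, function(p) {
    if (!length(p)) structure(character(), names = character())
    else p[order(names(p))]
  })
  g <- structure(
    list(ids = ids, name = name, namespace = namespace, obsolete = obsolete,
         parents = parents, alt = alt, subsets = subsets, roots = character()),
    class = "ontology_graph")
  validate_ontology(g)
}

validate_ontology <- function(g) {
  if (length(g$alt)) {
    if (anyDuplicated(names(g$alt)))
      stop("alt_id mapped to more than one primary term: ",
           paste(unique(names(g$alt)[duplicated(names(g$alt))]), collapse = ", "))
    if (any(names(g$alt) %in% g$ids))
      stop("alt_id collides with a primary term id: ",
           paste(intersect(names(g$alt), g$ids), collapse = ", "))
    bad <- setdiff(g$alt, g$ids)
    if (length(bad))
      stop("alt_id points to unknown primary term: ", paste(bad, collapse = ", "))
  }
  # obsolete terms carry no edges
  for (id in g$ids[g$obsolete]) {
    if (length(g$parents[[id]]))
      stop("obsolete term ", id, " has parents")
  }
  edges <- ontology_edges(g)
  unknown <- setdiff(edges$parent, g$ids)
  if (length(unknown))
    stop("parent reference to unknown term: ", paste(unknown, collapse = ", "))
  if (nrow(edges)) {
    ig <- igraph::graph_from_data_frame(
      edges[, c("child", "parent")], directed = TRUE,
      vertices = data.frame(name = g$ids))
    if (!igraph::is_dag(ig))
      stop("ontology graph contains a cycle")
  }
  ns_bad <- vapply(seq_len(nrow(edges)), function(i) {
    g$namespace[[edges$child[i]]] != g$namespace[[edges$parent[i]]]
  }, logical(1))
  if (any(ns_bad))
    stop("edge crosses namespaces: ",
         paste(edges$child[ns_bad], edges$parent[ns_bad], sep = "->",
               collapse = ", "))
  live <- g$ids[!g$obsolete]
  has_parent <- vapply(g$parents[live], length, integer(1)) > 0L
  roots <- live[!has_parent]
  g$roots <- vapply(split(roots, g$namespace[roots]), function(r) {
    if (length(r) > 1L)
      stop("namespace has multiple roots: ", paste(r, collapse = ", "))
    r
  }, character(1))
  g
}

# long-form edge table: child, parent, relation
ontology_edges <- function(g) {
  np <- vapply(g$parents, length, integer(1))
  data.frame(
    child = rep(g$ids, np),
    parent = unlist(lapply(g$parents, names), use.names = FALSE),
    relation = unlist(g$parents, use.names = FALSE),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Parse a Gene Ontology OBO 1.2 file
#'
#' Loads all `[Term]` stanzas.  `is_a` and `relationship: part_of` edges are
#' retained; other relationship types are dropped.  Obsolete terms are kept,
#' flagged, and carry no edges.  Alternative ids (`alt_id`) are resolved to
#' their primary id at parse time, so all downstream operations see primary
#' ids only.
#'
#' @param path path to an OBO 1.2 file.
#' @return an `ontology_graph` object: term ids, names, namespaces,
#'   obsolete flags, typed parent edges, alt-id map, subset (slim) tags and
#'   the per-namespace root terms.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "", "[Term]", "id: GO:0000001",
#'   "name: root", "namespace: biological_process", "", "[Term]",
#'   "id: GO:0000002", "name: child", "namespace: biological_process",
#'   "is_a: GO:0000001 ! root"), obo)
#' g <- parse_obo(obo)
#' ancestors(g, "GO:0000002")
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stanza_start <- grep("^\\[", lines)
  terms <- list()
  in_term <- FALSE
  cur <- NULL
  cur_line <- NA_integer_
  flush <- function(cur, cur_line) {
    if (is.null(cur)) return(invisible(NULL))
    if (is.null(cur$id))
      stop("malformed [Term] stanza starting at line ", cur_line,
           ": missing id")
    terms[[length(terms) + 1L]] <<- cur
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    line <- sub("\\s+$", "", lines[i])
    if (line == "" || grepl("^!", line)) next
    if (grepl("^\\[", line)) {
      flush(cur, cur_line)
      cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) {
        cur <- list(parents = character(), alt = character(),
                    subsets = character(), obsolete = FALSE)
        cur_line <- i
      }
      next
    }
    if (!in_term) next
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1]]
    if (length(m) != 3L)
      stop("malformed tag-value line in OBO file at line ", i, ": ", line)
    key <- m[2]
    val <- sub("\\s*!.*$", "", m[3])   # strip trailing comment
    if (key == "id") {
      if (!is_term_id(val))
        stop("invalid term id at line ", i, ": ", val)
      cur$id <- val
    } else if (key == "name") {
      cur$name <- m[3]
    } else if (key == "namespace") {
      if (!val %in% GO_NAMESPACES)
        stop("unknown namespace at line ", i, ": ", val)
      cur$namespace <- val
    } else if (key == "is_a") {
      p <- cur$parents
      p[val] <- "is_a"
      cur$parents <- p
    } else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) < 2L)
        stop("malformed relationship at line ", i, ": ", val)
      if (parts[1] == "part_of") {
        p <- cur$parents
        p[parts[2]] <- "part_of"
        cur$parents <- p
      }
    } else if (key == "alt_id") {
      cur$alt <- c(cur$alt, val)
    } else if (key == "subset") {
      cur$subsets <- c(cur$subsets, val)
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(val, "true")
    }
    # other tags (def, synonym, xref, ...) are ignored
  }
  flush(cur, cur_line)
  if (!length(terms)) stop("no [Term] stanzas found in ", path)

  ids <- vapply(terms, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate term id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  name <- vapply(terms, function(t) t$name %||% t$id, character(1))
  namespace <- vapply(terms, function(t) t$namespace %||% NA_character_,
                      character(1))
  if (anyNA(namespace))
    stop("term without namespace: ",
         paste(ids[is.na(namespace)], collapse = ", "))
  obsolete <- vapply(terms, `[[`, logical(1), "obsolete")
  alt <- unlist(lapply(seq_along(terms), function(j) {
    a <- terms[[j]]$alt
    if (!length(a)) return(NULL)
    structure(rep(ids[j], length(a)), names = a)
  }))
  if (is.null(alt)) alt <- character()
  parents <- lapply(seq_along(terms), function(j) {
    if (obsolete[j]) return(character())   # obsolete: flagged, edge-less
    p <- terms[[j]]$parents
    if (!length(p)) return(character())
    # parents may be referenced through an alt_id
    pn <- names(p)
    resolved <- ifelse(pn %in% ids, pn,
                       ifelse(pn %in% names(alt), alt[pn], pn))
    names(p) <- resolved
    p[!duplicated(names(p))]
  })
  names(parents) <- ids
  subsets <- lapply(terms, `[[`, "subsets")
  names(subsets) <- ids
  new_ontology_graph(ids, name, namespace, obsolete, parents, alt, subsets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", length(x$ids), "terms (",
      sum(x$obsolete), "obsolete ),",
      nrow(ontology_edges(x)), "edges\n")
  ns <- table(x$namespace[!x$obsolete])
  cat("  namespaces:", paste(names(ns), ns, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Resolve a term id (following alt_ids) to its primary id
#'
#' @param graph an `ontology_graph`.
#' @param term a term id, possibly an alternative id.
#' @param error if `TRUE`, unknown ids raise an error; otherwise `NA`.
#' @return the primary term id.
#' @export
resolve_term <- function(graph, term, error = TRUE) {
  out <- ifelse(term %in% graph$ids, term,
                ifelse(term %in% names(graph$alt), graph$alt[term],
                       NA_character_))
  if (error && anyNA(out))
    stop("unknown term id: ", paste(term[is.na(out)], collapse = ", "))
  unname(out)
}

#' Look up a term record by id or alt id
#' @inheritParams resolve_term
#' @return a list with id, name, namespace, parents, obsolete.
#' @export
term_info <- function(graph, term) {
  id <- resolve_term(graph, term)
  list(id = id, name = unname(graph$name[id]),
       namespace = unname(graph$namespace[id]),
       parents = graph$parents[[id]], obsolete = unname(graph$obsolete[id]))
}

# Ancestor closures for many terms at once, with shared memoisation.
# Returns a named list id -> character vector of ancestors (excluding self).
term_closures <- function(graph, ids, relations = GO_RELATIONS) {
  memo <- new.env(parent = emptyenv())
  clo <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    p <- graph$parents[[id]]
    par <- as.character(names(p)[p %in% relations])
    res <- par
    for (q in par) res <- union(res, clo(q))
    memo[[id]] <- res
    res
  }
  out <- lapply(ids, clo)
  names(out) <- ids
  out
}

#' Ancestors of a term in the GO DAG
#'
#' All terms reachable from `term` by following one or more parent edges of
#' the selected relation types; the term itself is excluded.
#'
#' @param graph an `ontology_graph`.
#' @param term a term id (alt ids are resolved).
#' @param relations relation types to traverse (default `is_a` + `part_of`).
#' @return character vector of ancestor term ids.
#' @export
ancestors <- function(graph, term, relations = GO_RELATIONS) {
  id <- resolve_term(graph, term)
  sort(term_closures(graph, id, relations)[[1]])
}

#' Annotation table constructor
#'
#' Holds a genome's direct gene-to-GO-term associations as a long-form
#' record table (one row per gene/term/evidence triple).
#'
#' @param records data.frame with columns `gene`, `term`, `evidence`
#'   (optional column `withfrom` carries the source reference gene of a
#'   transferred annotation).
#' @param genome_id label of the annotated genome.
#' @param source free-text provenance label.
#' @return an `annotation_table`.
#' @export
annotation_table <- function(records, genome_id = "genome",
                             source = "unknown") {
  if (is.null(records) || !nrow(records)) {
    records <- data.frame(gene = character(), term = character(),
                          evidence = character(), withfrom = character(),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "term") %in% names(records)))
  if (is.null(records$evidence)) records$evidence <- ""
  if (is.null(records$withfrom)) records$withfrom <- ""
  records <- unique(records[, c("gene", "term", "evidence", "withfrom")])
  records <- records[order(records$gene, records$term, records$evidence), ,
                     drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, genome_id = genome_id, source = source),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("annotation_table [", x$genome_id, "]: ",
      length(unique(x$records$gene)), " genes, ",
      length(unique(x$records$term)), " distinct terms",
      if (isTRUE(attr(x, "propagated"))) " (propagated)", "\n", sep = "")
  invisible(x)
}

#' Gene-to-term sets of an annotation table
#' @param table an `annotation_table`.
#' @return named list gene -> character vector of term ids.
#' @export
gene_terms <- function(table) {
  lapply(split(table$records$term, table$records$gene), unique)
}

#' True-path propagation of an annotation table
#'
#' Replaces every gene's term set by its ancestor closure (each annotated
#' term plus all its ancestors over the selected relations).  The result is
#' ancestor-closed and idempotent under re-application.  Terms annotated to
#' obsolete ontology entries are dropped with a warning: obsolete terms
#' neither receive nor propagate annotation.
#'
#' @param table an `annotation_table` (term ids may be alt ids).
#' @param graph an `ontology_graph`.
#' @param relations relations to traverse.
#' @param on_missing `"error"` (default) or `"skip"` (drop with a warning)
#'   for annotated terms absent from the graph.
#' @return a propagated `annotation_table` (attribute `propagated` = TRUE);
#'   propagated rows inherit the evidence of the record they derive from.
#' @export
propagate <- function(table, graph, relations = GO_RELATIONS,
                      on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  rec <- table$records
  if (!nrow(rec)) {
    out <- annotation_table(rec, table$genome_id, table$source)
    attr(out, "propagated") <- TRUE
    return(out)
  }
  prim <- resolve_term(graph, rec$term, error = FALSE)
  if (anyNA(prim)) {
    missing <- unique(rec$term[is.na(prim)])
    if (on_missing == "error")
      stop("annotated term absent from ontology: ",
           paste(missing, collapse = ", "))
    warning("dropping ", length(missing),
            " annotated term(s) absent from ontology: ",
            paste(missing, collapse = ", "))
    rec <- rec[!is.na(prim), , drop = FALSE]
    prim <- prim[!is.na(prim)]
  }
  rec$term <- prim
  obs <- graph$obsolete[rec$term]
  if (any(obs)) {
    warning("dropping annotation to obsolete term(s): ",
            paste(unique(rec$term[obs]), collapse = ", "))
    rec <- rec[!obs, , drop = FALSE]
  }
  if (!nrow(rec)) {
    out <- annotation_table(rec, table$genome_id, table$source)
    attr(out, "propagated") <- TRUE
    return(out)
  }
  clo <- term_closures(graph, unique(rec$term), relations)
  n_anc <- vapply(clo[rec$term], length, integer(1))
  prop <- data.frame(
    gene = c(rec$gene, rep(rec$gene, n_anc)),
    term = c(rec$term, unlist(clo[rec$term], use.names = FALSE)),
    evidence = c(rec$evidence, rep(rec$evidence, n_anc)),
    withfrom = c(rec$withfrom, rep(rec$withfrom, n_anc)),
    stringsAsFactors = FALSE)
  out <- annotation_table(prop, table$genome_id, table$source)
  attr(out, "propagated") <- TRUE
  out
}

#' Count distinct annotated terms in a table
#'
#' @param table an `annotation_table` (usually propagated).
#' @param graph optional `ontology_graph`; required when `drop_roots`.
#' @param drop_roots exclude the namespace root terms from the count.
#' @return integer count of distinct term ids.
#' @export
n_distinct_terms <- function(table, graph = NULL, drop_roots = FALSE) {
  terms <- unique(table$records$term)
  if (drop_roots) {
    stopifnot(!is.null(graph))
    terms <- setdiff(terms, graph$roots)
  }
  length(terms)
}

#' Reduce a term set to its most specific members
#'
#' Removes every term that is an ancestor (over the selected relations) of
#' another term in the set; the result is an antichain of the DAG.  Used to
#' strip redundant high-level terms from enrichment results.
#'
#' @param terms character vector of term ids.
#' @param graph an `ontology_graph`.
#' @param relations relations to traverse.
#' @return sorted character vector, subset of `terms`.
#' @export
reduce_to_most_specific <- function(terms, graph, relations = GO_RELATIONS) {
  ids <- unique(resolve_term(graph, terms))
  if (!length(ids)) return(character())
  clo <- term_closures(graph, ids, relations)
  anc <- unique(unlist(clo, use.names = FALSE))
  sort(setdiff(ids, anc))
}

#' GO-slim set constructor
#' @param members character vector of slim term ids.
#' @param name label for the slim set.
#' @param graph optional `ontology_graph` to validate members against.
#' @return a `slim_set`.
#' @export
slim_set <- function(members, name = "slim", graph = NULL) {
  members <- unique(members)
  if (!all(is_term_id(members)))
    stop("invalid slim term id: ",
         paste(members[!is_term_id(members)], collapse = ", "))
  if (!is.null(graph)) members <- resolve_term(graph, members)
  structure(list(name = name, members = sort(unique(members))),
            class = "slim_set")
}

#' Read a slim set from a one-id-per-line file
#' @param path file with one GO id per line; `#` starts a comment.
#' @inheritParams slim_set
#' @export
read_slim <- function(path, name = basename(path), graph = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  slim_set(lines[nzchar(lines)], name = name, graph = graph)
}

#' Extract a slim set from OBO subset tags
#' @param graph an `ontology_graph` parsed from an OBO file.
#' @param subset the subset tag, e.g. `"goslim_generic"`.
#' @export
slim_from_subset <- function(graph, subset = "goslim_generic") {
  members <- graph$ids[vapply(graph$subsets[graph$ids],
                              function(s) subset %in% s, logical(1))]
  if (!length(members))
    stop("no terms tagged with subset ", subset)
  slim_set(members, name = subset, graph = graph)
}

#' Single-occurrence GO-slim counting
#'
#' For each input term, every slim term that equals it or lies among its
#' ancestors is credited at most once for that input term ("single
#' occurrence" counting); returned counts are sums over input terms.
#'
#' @param terms character vector of term ids (a set; duplicated ids are
#'   counted once).
#' @param slim a `slim_set`.
#' @param graph an `ontology_graph`.
#' @param relations relations to traverse.
#' @return named integer vector over the slim members (zeros included).
#' @export
slim_count <- function(terms, slim, graph, relations = GO_RELATIONS) {
  members <- resolve_term(graph, slim$members)
  counts <- structure(integer(length(members)), names = members)
  if (!length(members)) return(counts)
  ids <- unique(resolve_term(graph, terms))
  if (!length(ids)) return(counts)
  clo <- term_closures(graph, ids, relations)
  for (id in ids) {
    hit <- intersect(members, c(id, clo[[id]]))
    counts[hit] <- counts[hit] + 1L
  }
  counts
}
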