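# Projection of a reference genome's GO annotation onto all members of
# each Jaccard orthologous cluster, plus annotation file IO and mapping
# summaries.

#' Transfer reference GO annotation across ortholog clusters
#'
#' Every Jaccard orthologous cluster receives the union of the direct term
#' sets of its reference-genome members, and every member protein
#' (reference proteins included, by default) is annotated with exactly that
#' set, so that all proteins of a cluster share identical GO terms.
#' Transferred records carry a computational evidence code (`IEA`) and the
#' source reference gene ids in the `withfrom` field.  Annotated reference
#' genes that sit in no cluster are counted as unmapped.
#'
#' @param oclusters an `ortholog_clusters` object.
#' @param reference an `annotation_table` of direct annotation for the
#'   reference genome.
#' @param proteomes data.frame `genome`, `protein`; must include the
#'   reference genome.
#' @param reference_genome label of the reference genome.
#' @param keep_reference_direct if `TRUE`, the reference genome keeps its
#'   original direct annotation instead of the (possibly larger)
#'   cluster-level union.
#' @return named list genome -> `annotation_table`; attributes
#'   `unmapped_genes` (annotated reference genes outside any cluster) and
#'   `mapped_genes` (annotated reference genes inside clusters).
#' @export
transfer_annotations <- function(oclusters, reference, proteomes,
                                 reference_genome,
                                 keep_reference_direct = FALSE) {
  if (!reference_genome %in% proteomes$genome)
    stop("reference genome ", reference_genome, " not among proteomes")
  cl <- oclusters$clusters
  ref_terms <- gene_terms(reference)
  annotated <- names(ref_terms)

  ref_rows <- cl[cl$genome == reference_genome, , drop = FALSE]
  mapped <- intersect(annotated, ref_rows$protein)
  unmapped <- setdiff(annotated, ref_rows$protein)

  # cluster-level term unions from annotated reference members
  ref_ann <- ref_rows[ref_rows$protein %in% annotated, , drop = FALSE]
  cl_terms <- lapply(split(ref_ann$protein, ref_ann$ortholog_id),
                     function(genes) sort(unique(unlist(ref_terms[genes]))))
  cl_source <- lapply(split(ref_ann$protein, ref_ann$ortholog_id),
                      function(genes) paste(sort(unique(genes)),
                                            collapse = "|"))

  genomes <- sort(unique(proteomes$genome))
  out <- lapply(genomes, function(g) {
    rows <- cl[cl$genome == g & cl$ortholog_id %in% names(cl_terms), ,
               drop = FALSE]
    nt <- vapply(cl_terms[rows$ortholog_id], length, integer(1))
    rec <- data.frame(
      gene = rep(rows$protein, nt),
      term = unlist(cl_terms[rows$ortholog_id], use.names = FALSE),
      evidence = "IEA",
      withfrom = rep(unlist(cl_source[rows$ortholog_id], use.names = FALSE),
                     nt),
      stringsAsFactors = FALSE)
    if (g == reference_genome && keep_reference_direct)
      return(annotation_table(reference$records, g,
                              source = reference$source))
    annotation_table(rec, g,
                     source = paste0("transferred from ", reference_genome))
  })
  names(out) <- genomes
  attr(out, "unmapped_genes") <- sort(unmapped)
  attr(out, "mapped_genes") <- sort(mapped)
  out
}

#' Summarise per-row mapping counts
#'
#' Computes the derived columns and aggregates of a mapping summary from
#' per-genome counts: percent annotated (`round(100 * annotated /
#' predicted)`), and, over the non-reference rows, the mean/min/max
#' annotated gene count and mean distinct term count.
#'
#' @param rows data.frame with columns `genome`, `predicted`, `annotated`,
#'   `terms` (distinct propagated term count).
#' @param reference_genome the `genome` value of the reference row.
#' @return a `mapping_summary` list: `$rows` (with `percent` added),
#'   `$mean_annotated`, `$min_annotated`, `$max_annotated`, `$mean_terms`
#'   (aggregates over non-reference rows, unrounded).
#' @export
summarize_mapping_rows <- function(rows, reference_genome) {
  stopifnot(all(c("genome", "predicted", "annotated", "terms") %in%
                  names(rows)))
  if (!reference_genome %in% rows$genome)
    stop("reference genome ", reference_genome, " not among rows")
  rows$percent <- percent_rounded(rows$annotated, rows$predicted)
  other <- rows[rows$genome != reference_genome, , drop = FALSE]
  structure(list(
    rows = rows,
    reference_genome = reference_genome,
    mean_annotated = mean(other$annotated),
    min_annotated = if (nrow(other)) min(other$annotated) else NA_integer_,
    max_annotated = if (nrow(other)) max(other$annotated) else NA_integer_,
    mean_terms = mean(other$terms)),
    class = "mapping_summary")
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat("mapping_summary (reference: ", x$reference_genome, ")\n", sep = "")
  print.data.frame(x$rows)
  cat(sprintf("non-reference genomes: mean annotated %s (range %s-%s), mean terms %s\n",
              round(x$mean_annotated), x$min_annotated, x$max_annotated,
              round(x$mean_terms)))
  invisible(x)
}

#' Mapping summary from annotation tables
#'
#' Builds the per-genome rows (predicted transcript count, GO-annotated
#' count, percent annotated, distinct propagated term count) and
#' cross-genome aggregates, plus the namespace shares (BP/MF/CC, rounded
#' percent) of the reference genome's propagated term list.
#'
#' @param tables named list genome -> `annotation_table` (direct
#'   annotation; propagation is applied internally).
#' @param proteomes data.frame `genome`, `protein`.
#' @param graph an `ontology_graph`.
#' @param reference_genome label of the reference genome.
#' @param drop_roots exclude the three namespace roots from distinct-term
#'   counts.
#' @return a `mapping_summary` with an additional `$namespace_share`
#'   element: named integer percents over the reference's propagated terms.
#' @export
mapping_summary <- function(tables, proteomes, graph, reference_genome,
                            drop_roots = FALSE) {
  genomes <- sort(names(tables))
  prop <- lapply(tables, propagate, graph = graph)
  rows <- do.call(rbind, lapply(genomes, function(g) {
    data.frame(genome = g,
               predicted = sum(proteomes$genome == g),
               annotated = length(unique(tables[[g]]$records$gene)),
               terms = n_distinct_terms(prop[[g]], graph, drop_roots),
               stringsAsFactors = FALSE)
  }))
  out <- summarize_mapping_rows(rows, reference_genome)
  ref_terms <- unique(prop[[reference_genome]]$records$term)
  if (drop_roots) ref_terms <- setdiff(ref_terms, graph$roots)
  ns <- table(factor(graph$namespace[ref_terms], levels = GO_NAMESPACES))
  out$namespace_share <- structure(
    percent_rounded(as.integer(ns), length(ref_terms)), names = names(ns))
  out$namespace_counts <- structure(as.integer(ns), names = names(ns))
  out
}

#' Write an annotation table (GAF 2.x, GMT or gene-to-terms)
#'
#' Output is byte-deterministic: rows are emitted in sorted gene/term
#' order, and the GAF date column comes from the table's `gaf_date`
#' attribute (default `"20110101"`) rather than the wall clock.
#'
#' @param table an `annotation_table`.
#' @param path output path.
#' @param format `"gaf"` (17-column GAF 2.x with `!`-prefixed header),
#'   `"gmt"` (one term per line: id, description, member genes) or
#'   `"gene2terms"` (gene TAB comma-separated term ids).
#' @param graph optional `ontology_graph`, used for GAF aspect letters and
#'   GMT descriptions.
#' @param taxon NCBI taxon column value for GAF.
#' @return the path, invisibly.
#' @export
write_annotation <- function(table, path,
                             format = c("gaf", "gmt", "gene2terms"),
                             graph = NULL, taxon = "taxon:0") {
  format <- match.arg(format)
  rec <- table$records
  if (!nrow(rec)) stop("annotation table is empty")
  rec <- rec[order(rec$gene, rec$term, rec$evidence), , drop = FALSE]
  if (format == "gaf") {
    aspect <- rep("", nrow(rec))
    if (!is.null(graph)) {
      ns <- graph$namespace[resolve_term(graph, rec$term, error = FALSE)]
      aspect <- c(biological_process = "P", molecular_function = "F",
                  cellular_component = "C")[ns]
      aspect[is.na(aspect)] <- ""
    }
    date <- attr(table, "gaf_date") %||% "20110101"
    lines <- c(
      "!gaf-version: 2.0",
      paste0("!generated-by: orthogo (", table$source, ")"),
      paste(table$genome_id,            # 1 DB
            rec$gene,                   # 2 DB object id
            rec$gene,                   # 3 symbol
            "",                         # 4 qualifier
            rec$term,                   # 5 GO id
            "ORTHOGO:0000001",          # 6 reference
            rec$evidence,               # 7 evidence code
            rec$withfrom,               # 8 with/from
            aspect,                     # 9 aspect
            "",                         # 10 name
            "",                         # 11 synonym
            "protein",                  # 12 type
            taxon,                      # 13 taxon
            date,                       # 14 date
            "orthogo",                  # 15 assigned by
            "",                         # 16 annotation extension
            "",                         # 17 gene product form id
            sep = "\t"))
    writeLines(lines, path)
  } else if (format == "gmt") {
    sets <- lapply(split(rec$gene, rec$term), function(g) sort(unique(g)))
    terms <- sort(names(sets))
    desc <- if (is.null(graph)) terms else {
      prim <- resolve_term(graph, terms, error = FALSE)
      ifelse(is.na(prim), terms, unname(graph$name[prim]))
    }
    lines <- vapply(seq_along(terms), function(i) {
      paste(c(terms[i], desc[i], sets[[terms[i]]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
  } else {
    sets <- lapply(split(rec$term, rec$gene), function(t) sort(unique(t)))
    genes <- sort(names(sets))
    lines <- vapply(genes, function(g) {
      paste0(g, "\t", paste(sets[[g]], collapse = ","))
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Parse a GAF 2.x annotation file
#'
#' Rows whose qualifier contains `NOT` are excluded.  Column 2 is the gene
#' id, column 5 the term id, column 7 the evidence code, column 8 the
#' with/from field.
#'
#' @param path GAF file; `!`-prefixed lines are headers.
#' @param genome_id genome label for the resulting table.
#' @return an `annotation_table`.
#' @export
parse_gaf <- function(path, genome_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  data_idx <- which(!startsWith(lines, "!") & nzchar(lines))
  if (!length(data_idx))
    return(annotation_table(NULL, genome_id %||% "genome",
                            source = basename(path)))
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  # trailing empty fields may be trimmed by strsplit; pad 15..17 to 17
  bad <- nf < 15L | nf > 17L
  if (any(bad))
    stop("GAF line ", data_idx[which(bad)[1]], " has ", nf[which(bad)[1]],
         " columns (expected 17)")
  rec <- data.frame(
    db = vapply(fields, `[[`, character(1), 1L),
    gene = vapply(fields, `[[`, character(1), 2L),
    qualifier = vapply(fields, `[[`, character(1), 4L),
    term = vapply(fields, `[[`, character(1), 5L),
    evidence = vapply(fields, `[[`, character(1), 7L),
    withfrom = vapply(fields, `[[`, character(1), 8L),
    stringsAsFactors = FALSE)
  rec <- rec[!grepl("(^|\\|)NOT($|\\|)", rec$qualifier), , drop = FALSE]
  if (is.null(genome_id)) {
    genome_id <- if (nrow(rec)) rec$db[1] else "genome"
  }
  annotation_table(rec[, c("gene", "term", "evidence", "withfrom")],
                   genome_id, source = basename(path))
}

#' Parse a GMT gene-set file into an annotation table
#' @param path GMT file (term, description, genes; tab-separated).
#' @param genome_id genome label.
#' @return an `annotation_table` (evidence is empty).
#' @export
parse_gmt <- function(path, genome_id = "genome") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rec <- do.call(rbind, lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    data.frame(gene = f[-(1:2)], term = f[1], stringsAsFactors = FALSE)
  }))
  annotation_table(rec, genome_id, source = basename(path))
}

#' Parse a gene-to-terms file into an annotation table
#' @param path file of `gene TAB comma-separated-term-ids` lines.
#' @param genome_id genome label.
#' @return an `annotation_table` (evidence is empty).
#' @export
parse_gene2terms <- function(path, genome_id = "genome") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rec <- do.call(rbind, lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L)
      stop("gene2terms line ", i, " must have 2 tab-separated fields")
    data.frame(gene = f[1], term = strsplit(f[2], ",", fixed = TRUE)[[1]],
               stringsAsFactors = FALSE)
  }))
  annotation_table(rec, genome_id, source = basename(path))
}
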