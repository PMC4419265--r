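# Readers and writers for the pipeline's plain-text formats: expression
# and annotation TSV, candidate edge lists (TSV / SIF), weighted network
# TSV / SIF / GraphML, IDN tables and ranking tables.

#' Write / read an expression set as TSV
#'
#' The expression table has a `gene` column followed by one column per
#' sample; the annotation table has columns `sampleID, condition, day,
#' replicate`.
#'
#' @param eset an [expr_set()].
#' @param expr_path,annot_path file paths.
#' @return `read_expression`: an [expr_set()]; `write_expression`: the
#'   paths, invisibly.
#' @export
write_expression <- function(eset, expr_path, annot_path) {
  stopifnot(inherits(eset, "expr_set"))
  df <- data.frame(gene = rownames(eset$values), eset$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(eset$annotations, annot_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(expr_path, annot_path))
}

#' @rdname write_expression
#' @export
read_expression <- function(expr_path, annot_path) {
  for (p in c(expr_path, annot_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  df <- utils::read.table(expr_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene") {
    stop("expression table must start with a 'gene' column: ", expr_path)
  }
  values <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric expression values in ",
                                expr_path)
  rownames(values) <- df$gene
  ann <- utils::read.table(annot_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  expr_set(values, ann)
}

# Deduplicate undirected edges and drop self-loops, reporting counts.
clean_edges <- function(edges, what = "candidate") {
  n0 <- nrow(edges)
  loops <- edges$source == edges$target
  edges <- edges[!loops, , drop = FALSE]
  keys <- pair_key(edges$source, edges$target)
  dup <- duplicated(keys)
  edges <- edges[!dup, , drop = FALSE]
  if (any(loops) || any(dup)) {
    message(what, " edges: dropped ", sum(loops), " self-loop(s) and ",
            sum(dup), " duplicate(s) of ", n0)
  }
  a <- pmin(edges$source, edges$target)
  b <- pmax(edges$source, edges$target)
  out <- data.frame(source = a, target = b, stringsAsFactors = FALSE)
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a candidate interaction edge list
#'
#' Accepts SIF (`geneA<TAB>pp<TAB>geneB`, extension `.sif`) or a
#' two-column TSV with header `source`, `target`.  Undirected duplicates
#' and self-loops are removed with a message.
#'
#' @param path file path.
#' @return data frame `source, target` of unique undirected pairs.
#' @export
read_candidate_network <- function(path) {
  if (!file.exists(path)) stop("candidate network file not found: ", path)
  if (grepl("\\.sif$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "[\t ]+")
    bad <- which(lengths(parts) != 3L)
    if (length(bad)) {
      stop("malformed SIF line ", bad[1L], " in ", path,
           ": expected 'source relation target'")
    }
    edges <- data.frame(source = vapply(parts, `[[`, "", 1L),
                        target = vapply(parts, `[[`, "", 3L),
                        stringsAsFactors = FALSE)
  } else {
    edges <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    if (!all(c("source", "target") %in% names(edges))) {
      stop("candidate TSV needs 'source' and 'target' columns: ", path)
    }
  }
  clean_edges(edges)
}

#' @rdname read_candidate_network
#' @param edges data frame with columns `source`, `target`.
#' @param format `"tsv"` or `"sif"`.
#' @export
write_candidate_network <- function(edges, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  edges <- as.data.frame(edges)
  if (format == "sif") {
    writeLines(paste(edges$source, "pp", edges$target, sep = "\t"), path)
  } else {
    utils::write.table(edges[, c("source", "target")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a fitted stage network
#'
#' `tsv` writes `source, target, b, stage`; `sif` writes the interaction
#' triples; `graphml` writes an igraph GraphML file (Cytoscape
#' compatible) with `b` as an edge attribute.
#'
#' @param net a `stage_network`.
#' @param path file path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  ed <- network_edges(net)
  if (format == "tsv") {
    utils::write.table(ed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    writeLines(paste(ed$source, "pp", ed$target, sep = "\t"), path)
  } else {
    g <- igraph::graph_from_data_frame(ed[, c("source", "target", "b")],
                                       directed = TRUE,
                                       vertices = net$genes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a weighted network TSV written by [write_network()]
#'
#' @param path file path.
#' @param genes optional gene universe; defaults to the genes present in
#'   the edge list.
#' @return a `stage_network`.
#' @export
read_network_tsv <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("network file not found: ", path)
  ed <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("source", "target", "b") %in% names(ed))) {
    stop("network TSV needs columns source, target, b: ", path)
  }
  stage <- if ("stage" %in% names(ed) && nrow(ed)) ed$stage[1L] else NA
  genes <- genes %||% sort(unique(c(ed$source, ed$target)))
  stage_network_from_edges(genes, ed, stage)
}

#' Write an IDN edge table
#'
#' Columns: `source, target, b1, b2, d, direction, existence`.
#'
#' @param idn an [compute_idn()] result.
#' @param path file path.
#' @export
write_idn <- function(idn, path) {
  stopifnot(inherits(idn, "idn"))
  utils::write.table(idn$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a ranking table (proteins or modules) as TSV
#'
#' @param table data frame from [rank_proteins()] or [rank_modules()].
#' @param path file path.
#' @export
write_ranking <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
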