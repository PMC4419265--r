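#' Gene set collection
#'
#' @param sets named list of character vectors (module -> members);
#'   names unique, every set nonempty.
#' @param description optional named character vector of descriptions.
#' @param source provenance string.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL,
                                source = "in-memory") {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  if (anyDuplicated(names(sets))) stop("gene set names must be unique")
  if (any(lengths(sets) == 0L)) stop("every gene set must be nonempty")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  description <- description %||%
    stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, description = description, source = source),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets (",
      paste(range(lengths(x$sets)), collapse = "-"), "genes ) from",
      x$source, "\n")
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' GMT is tab-delimited: set name, description, then member genes.
#'
#' @param path file path.
#' @return `read_gmt`: a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1L], " in ", path,
         " (need name, description, >=1 gene)")
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  desc <- stats::setNames(vapply(parts, `[[`, character(1L), 2L),
                          names(sets))
  gene_set_collection(sets, desc, source = path)
}

#' @rdname read_gmt
#' @param collection a [gene_set_collection()] or plain named list.
#' @export
write_gmt <- function(collection, path) {
  if (!inherits(collection, "gene_set_collection")) {
    collection <- gene_set_collection(collection)
  }
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]] %||% "",
            collection$sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Random gene set collection for validation runs
#'
#' Draws synthetic modules of random sizes from a gene universe; used to
#' exercise module scoring without an external annotation source.
#'
#' @param genes gene universe.
#' @param n_sets number of modules.
#' @param size_range inclusive range of module sizes.
#' @param seed integer seed.
#' @return a [gene_set_collection()].
#' @export
random_gene_sets <- function(genes, n_sets = 10L, size_range = c(5L, 15L),
                             seed = 1L) {
  stopifnot(is_count(n_sets, 1L), size_range[1] >= 1,
            size_range[2] <= length(genes))
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      sample(genes, sample(size_range[1]:size_range[2], 1L))
    })
    names(sets) <- sprintf("module%02d", seq_len(n_sets))
    gene_set_collection(sets, source = "random")
  })
}

#' Relevance score of a functional module
#'
#' The module score is the sum of the member proteins' relevance scores;
#' members absent from the IDN contribute zero.
#'
#' @param idn an [compute_idn()] result.
#' @param members nonempty character vector of member genes.
#' @return nonnegative scalar.
#' @export
relevance_score_module <- function(idn, members) {
  stopifnot(inherits(idn, "idn"), length(members) >= 1L)
  tab <- relevance_scores(idn)
  sum(tab$RS[tab$gene %in% members])
}

#' Hypergeometric enrichment of a module in the IDN gene set
#'
#' One-sided tail probability `P(X >= overlap)` of drawing at least the
#' observed number of module members when `|idn_genes|` genes are drawn
#' without replacement from the universe.
#'
#' @param idn_genes genes active in the IDN (the draw).
#' @param members module members; must lie within `universe`.
#' @param universe background gene set (nonempty).
#' @return p-value in `(0, 1]`.
#' @export
enrich_module <- function(idn_genes, members, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  members <- unique(members)
  idn_genes <- unique(idn_genes)
  if (!all(members %in% universe)) {
    stop("module members outside the universe: ",
         paste(utils::head(setdiff(members, universe), 5L), collapse = ", "))
  }
  if (!all(idn_genes %in% universe)) {
    stop("idn_genes outside the universe")
  }
  ov <- length(intersect(members, idn_genes))
  stats::phyper(ov - 1L, length(members),
                length(universe) - length(members), length(idn_genes),
                lower.tail = FALSE)
}

#' Score and rank functional modules on an IDN
#'
#' Every module gets its summed relevance score and a hypergeometric
#' enrichment p-value of its overlap with the IDN's active genes (those
#' with at least one changed interaction) against the universe (default:
#' all IDN genes).  Module members outside the universe are ignored for
#' the enrichment test.
#'
#' @param idn an [compute_idn()] result.
#' @param collection a [gene_set_collection()].
#' @param universe background genes; default `idn$genes`.
#' @param top_n number of rows to keep (default all).
#' @return data frame `rank, module, RS, n_members, n_in_idn, p`, sorted
#'   by descending score, ties broken by module name.
#' @export
rank_modules <- function(idn, collection, universe = NULL, top_n = Inf) {
  stopifnot(inherits(idn, "idn"),
            inherits(collection, "gene_set_collection"), top_n >= 1)
  if (!length(collection$sets)) {
    warning("empty gene set collection")
    return(data.frame(rank = integer(0), module = character(0),
                      RS = numeric(0), n_members = integer(0),
                      n_in_idn = integer(0), p = numeric(0)))
  }
  universe <- unique(universe %||% idn$genes)
  scores <- relevance_scores(idn)
  active <- intersect(scores$gene[scores$degree > 0], universe)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]
    in_universe <- intersect(members, universe)
    data.frame(module = nm,
               RS = relevance_score_module(idn, members),
               n_members = length(members),
               n_in_idn = length(intersect(members, active)),
               p = if (length(in_universe)) {
                 enrich_module(active, in_universe, universe)
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$RS, tab$module), , drop = FALSE]
  tab <- utils::head(tab, top_n)
  cbind(rank = seq_len(nrow(tab)), tab, row.names = NULL)
}
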