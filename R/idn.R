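#' Interaction difference network between two stages
#'
#' Embeds both stage matrices over the union gene set (a gene absent
#' from a stage contributes zero entries) and differences them:
#' `d_pq = b_pq(stage2) - b_pq(stage1)`.  Entries with `|d|` at or below
#' the noise floor are dropped.  Every remaining entry is labelled by
#' direction (`enhancing` if the activity increased, `attenuating` if it
#' decreased) and existence (`emerged` if absent before and present
#' after, `diminished` for the reverse, `coexisting` when present in
#' both).  Nodes are labelled the same way from their incident edges in
#' each stage.
#'
#' @param net1 stage network of the earlier stage.
#' @param net2 stage network of the later stage; its label must differ
#'   from `net1`'s.
#' @param b_floor magnitude treated as zero.
#' @return an object of class `idn`: list with `from`, `to`, `genes`
#'   (sorted union), `D` (sparse difference matrix), `edges`
#'   (`source, target, b1, b2, d, direction, existence`), `nodes`
#'   (`gene, status`).
#' @export
compute_idn <- function(net1, net2, b_floor = 1e-12) {
  stopifnot(inherits(net1, "stage_network"), inherits(net2, "stage_network"))
  if (identical(net1$stage, net2$stage)) {
    stop("the two networks must come from different stages")
  }
  genes <- sort(union(net1$genes, net2$genes))
  embed <- function(net) {
    s <- Matrix::summary(net$b)
    Matrix::sparseMatrix(i = match(net$genes[s$i], genes),
                         j = match(net$genes[s$j], genes),
                         x = s$x, dims = c(length(genes), length(genes)),
                         dimnames = list(genes, genes))
  }
  B1 <- embed(net1)
  B2 <- embed(net2)
  Dfull <- B2 - B1
  s <- Matrix::summary(Dfull)
  keep <- abs(s$x) > b_floor
  D <- Matrix::sparseMatrix(i = s$i[keep], j = s$j[keep], x = s$x[keep],
                            dims = dim(Dfull),
                            dimnames = list(genes, genes))
  b1 <- B1[cbind(s$i[keep], s$j[keep])]
  b2 <- B2[cbind(s$i[keep], s$j[keep])]
  cls <- classify_edge_change(ifelse(abs(b1) > b_floor, b1, NA_real_),
                              ifelse(abs(b2) > b_floor, b2, NA_real_))
  edges <- data.frame(source = genes[s$i[keep]], target = genes[s$j[keep]],
                      b1 = b1, b2 = b2, d = s$x[keep],
                      direction = cls$direction, existence = cls$existence,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  present <- function(B) {
    d <- Matrix::rowSums(abs(B) > b_floor) +
      Matrix::colSums(abs(B) > b_floor)
    d > 0
  }
  p1 <- present(B1)
  p2 <- present(B2)
  status <- rep("none", length(genes))
  status[p1 & p2] <- "coexisting"
  status[!p1 & p2] <- "emerged"
  status[p1 & !p2] <- "diminished"
  nodes <- data.frame(gene = genes, status = status,
                      stringsAsFactors = FALSE)
  structure(list(from = net1$stage, to = net2$stage, genes = genes,
                 D = D, edges = edges, nodes = nodes),
            class = "idn")
}

#' @export
print.idn <- function(x, ...) {
  cat("idn '", x$from, "' -> '", x$to, "': ", length(x$genes), " genes, ",
      nrow(x$edges), " changed interaction entries\n", sep = "")
  invisible(x)
}

#' Classify the change of one interaction between two stages
#'
#' Vectorised over edges.  `NA` encodes an absent interaction and is
#' treated as activity 0 for the direction call: `enhancing` when the
#' activity increased (`+ -> ++`, `-- -> -`, `0 -> +`, `- -> 0`),
#' `attenuating` when it decreased (`++ -> +`, `- -> --`, `+ -> 0`,
#' `0 -> -`), `none` when equal.  Existence is `emerged` (absent then
#' present), `diminished` (present then absent) or `coexisting`.
#'
#' @param b1,b2 activities in the earlier/later stage; `NA` = absent.
#'   Entries absent in both stages are an error.
#' @return data frame with columns `direction`, `existence`.
#' @export
classify_edge_change <- function(b1, b2) {
  stopifnot(length(b1) == length(b2))
  if (any(is.na(b1) & is.na(b2))) {
    stop("interaction absent in both stages cannot be classified")
  }
  v1 <- ifelse(is.na(b1), 0, b1)
  v2 <- ifelse(is.na(b2), 0, b2)
  direction <- ifelse(v2 > v1, "enhancing",
                      ifelse(v2 < v1, "attenuating", "none"))
  existence <- ifelse(is.na(b1), "emerged",
                      ifelse(is.na(b2), "diminished", "coexisting"))
  data.frame(direction = direction, existence = existence,
             stringsAsFactors = FALSE)
}

#' Relevance scores of all proteins in an IDN
#'
#' The relevance score of protein `p` is the summed magnitude of its
#' interaction-activity differences divided by its degree,
#' `RS_p = sum_q |d_pq| / degree(p)`, where the degree is the number of
#' nonzero entries in row `p` of the difference matrix; proteins with no
#' changed interaction score 0.  Equivalently, `RS_p` is the mean
#' absolute activity change over the protein's changed interactions.
#'
#' @param idn an [compute_idn()] result.
#' @return data frame `gene, RS, degree`.
#' @export
relevance_scores <- function(idn) {
  stopifnot(inherits(idn, "idn"))
  degree <- Matrix::rowSums(idn$D != 0)
  total <- Matrix::rowSums(abs(idn$D))
  rs <- ifelse(degree > 0, total / pmax(degree, 1L), 0)
  data.frame(gene = idn$genes, RS = as.numeric(rs),
             degree = as.integer(degree), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @rdname relevance_scores
#' @param gene a single gene identifier present in the IDN.
#' @return `relevance_score_protein`: the scalar score.
#' @export
relevance_score_protein <- function(idn, gene) {
  stopifnot(inherits(idn, "idn"))
  if (!gene %in% idn$genes) stop("gene '", gene, "' not in the IDN")
  tab <- relevance_scores(idn)
  tab$RS[match(gene, tab$gene)]
}

#' Rank proteins by relevance score
#'
#' @param idn an [compute_idn()] result.
#' @param top_n number of rows to return (default all).
#' @return data frame `rank, protein, RS, degree`, sorted by descending
#'   score with lexicographic tie-breaking.
#' @export
rank_proteins <- function(idn, top_n = Inf) {
  stopifnot(top_n >= 1)
  tab <- relevance_scores(idn)
  tab <- tab[order(-tab$RS, tab$gene), , drop = FALSE]
  tab <- utils::head(tab, top_n)
  data.frame(rank = seq_len(nrow(tab)), protein = tab$gene, RS = tab$RS,
             degree = tab$degree, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Extract the neighbourhood of seed proteins from an IDN
#'
#' Induced sub-IDN of all nodes within `radius` hops of any seed in the
#' undirected graph of changed interactions.  Seeds missing from the IDN
#' are skipped with a warning; a seed without changed interactions
#' yields itself as a singleton.
#'
#' @param idn an [compute_idn()] result.
#' @param seeds gene identifiers.
#' @param radius neighbourhood order, `>= 1`.
#' @return an `idn` restricted to the neighbourhood genes.
#' @export
extract_neighborhood <- function(idn, seeds, radius = 1L) {
  stopifnot(inherits(idn, "idn"), is_count(radius, 1L))
  missing <- setdiff(seeds, idn$genes)
  if (length(missing)) {
    warning("seed(s) not in the IDN, skipped: ",
            paste(missing, collapse = ", "))
    seeds <- setdiff(seeds, missing)
  }
  if (!length(seeds)) stop("no valid seeds")
  g <- igraph::graph_from_data_frame(
    idn$edges[, c("source", "target")], directed = FALSE,
    vertices = idn$genes)
  hoods <- igraph::ego(g, order = radius, nodes = seeds)
  keep <- sort(unique(unlist(lapply(hoods, function(v) names(v)))))
  sub <- idn
  sub$genes <- keep
  sub$D <- idn$D[keep, keep, drop = FALSE]
  sub$edges <- idn$edges[idn$edges$source %in% keep &
                           idn$edges$target %in% keep, , drop = FALSE]
  rownames(sub$edges) <- NULL
  sub$nodes <- idn$nodes[idn$nodes$gene %in% keep, , drop = FALSE]
  rownames(sub$nodes) <- NULL
  sub
}
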