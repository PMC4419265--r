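#' Expression set: gene x sample matrix with sample annotations
#'
#' Light container tying a numeric expression matrix to its per-sample
#' annotations (`sampleID`, `condition`, `day`, `replicate`).
#'
#' @param values numeric genes x samples matrix with dimnames.
#' @param annotations data frame with columns `sampleID`, `condition`,
#'   `day`, `replicate`; `sampleID` must match `colnames(values)`.
#' @return an object of class `expr_set`.
#' @export
expr_set <- function(values, annotations) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene rownames and sample colnames")
  }
  if (!all(is.finite(values))) stop("expression values must all be finite")
  req <- c("sampleID", "condition", "day", "replicate")
  if (!all(req %in% names(annotations))) {
    stop("annotations must have columns ", paste(req, collapse = ", "))
  }
  annotations <- as.data.frame(annotations)[, req]
  if (!identical(colnames(values), as.character(annotations$sampleID))) {
    stop("annotations$sampleID must match colnames(values) in order")
  }
  structure(list(values = values, annotations = annotations),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$values), "genes x", ncol(x$values), "samples;",
      length(unique(x$annotations$condition)), "conditions,",
      length(unique(x$annotations$day)), "days\n")
  invisible(x)
}

#' Quantile normalization
#'
#' Forces every sample (column) to share the same distribution: each
#' column's sorted values are replaced by the across-sample mean of the
#' order statistics, with ties receiving the mean of the reference values
#' at the tied ranks.  Delegates to [limma::normalizeQuantiles()].
#' Idempotent: a second application leaves the matrix unchanged.
#'
#' @param x numeric matrix or [expr_set()].
#' @return object of the same type with normalized values.
#' @export
quantile_normalize <- function(x) UseMethod("quantile_normalize")

#' @export
quantile_normalize.default <- function(x) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("quantile_normalize: non-finite input")
  if (ncol(x) < 2L) stop("quantile_normalize needs at least 2 samples")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' @export
quantile_normalize.expr_set <- function(x) {
  x$values <- quantile_normalize(x$values)
  x
}

#' Stage design: which (condition, day) cells compose a stage
#'
#' @param stage stage label.
#' @param condition,day parallel vectors of segments, days strictly
#'   increasing.
#' @return data frame with attribute `stage`, class `stage_design`.
#' @export
stage_design <- function(stage, condition, day) {
  stopifnot(length(condition) == length(day), length(day) >= 1L,
            all(diff(day) > 0))
  structure(data.frame(condition = condition, day = day,
                       stringsAsFactors = FALSE),
            stage = stage, class = c("stage_design", "data.frame"))
}

#' Default three-stage composition of the differentiation time course
#'
#' Stage I is the first condition alone across all seven days; stage II
#' takes days 0 and 1 from the first condition and days 3--13 from the
#' second; stage III takes days 0 and 1 from the first, day 3 from the
#' second and days 5--13 from the third.  Each stage is the time course a
#' cell population actually experienced under the corresponding induction
#' protocol.
#'
#' @param conditions the three condition labels, in induction order.
#' @return named list of three [stage_design()] objects (`I`, `II`, `III`).
#' @export
stage_designs <- function(conditions = c("LSB", "LSB/S/F8",
                                         "LSB/S/F8/CHIR")) {
  stopifnot(length(conditions) == 3L)
  list(
    I = stage_design("I", rep(conditions[1], 7L), c(0, 1, 3, 5, 7, 11, 13)),
    II = stage_design("II",
                      c(rep(conditions[1], 2L), rep(conditions[2], 5L)),
                      c(0, 1, 3, 5, 7, 11, 13)),
    III = stage_design("III",
                       c(rep(conditions[1], 2L), conditions[2],
                         rep(conditions[3], 4L)),
                       c(0, 1, 3, 5, 7, 11, 13)))
}

#' Stage profile: replicate-averaged gene x day matrix for one stage
#'
#' @param stage stage label.
#' @param genes gene identifiers.
#' @param days numeric time points.
#' @param values genes x days numeric matrix.
#' @param mrna optional genes x days matrix of a distinct mRNA series;
#'   when present, network fitting uses it for the translation column of
#'   the regression so that `alpha` and `beta` are separately
#'   identifiable.
#' @return object of class `stage_profile`.
#' @export
stage_profile <- function(stage, genes, days, values, mrna = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(genes), ncol(values) == length(days),
            all(diff(days) > 0))
  dimnames(values) <- list(genes, paste0("d", days))
  if (!is.null(mrna)) {
    mrna <- as.matrix(mrna)[, seq_along(days), drop = FALSE]
    stopifnot(nrow(mrna) == length(genes))
    dimnames(mrna) <- dimnames(values)
  }
  structure(list(stage = stage, genes = genes, days = as.numeric(days),
                 values = values, mrna = mrna),
            class = "stage_profile")
}

#' @export
print.stage_profile <- function(x, ...) {
  cat("stage_profile '", x$stage, "': ", length(x$genes), " genes x ",
      length(x$days), " time points (", x$days[1], "..",
      x$days[length(x$days)], ")",
      if (!is.null(x$mrna)) ", with mRNA series" else "", "\n", sep = "")
  invisible(x)
}

#' Assemble a stage profile from an expression set
#'
#' For every (condition, day) segment of the design, averages the
#' replicates of that cell into one column; columns are ordered by day.
#'
#' @param eset an [expr_set()].
#' @param design a [stage_design()].
#' @param genes optional subset of genes to keep (e.g. the stage's
#'   differentially expressed set).
#' @return a [stage_profile()].
#' @export
assemble_stage_profile <- function(eset, design, genes = NULL) {
  stopifnot(inherits(eset, "expr_set"), inherits(design, "stage_design"))
  ann <- eset$annotations
  vals <- eset$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(vals))
    if (length(missing)) {
      stop("genes not in the expression set: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    vals <- vals[genes, , drop = FALSE]
  }
  cols <- vapply(seq_len(nrow(design)), function(i) {
    sel <- ann$condition == design$condition[i] & ann$day == design$day[i]
    if (!any(sel)) {
      stop("no samples for condition '", design$condition[i], "' at day ",
           design$day[i])
    }
    rowMeans(vals[, sel, drop = FALSE])
  }, numeric(nrow(vals)))
  stage_profile(attr(design, "stage"), rownames(vals), design$day, cols)
}

#' One-way ANOVA differential expression filter with BH correction
#'
#' Tests, per gene, whether the mean expression differs across the
#' stage's (condition, day) cells (groups = time points of the stage
#' design, observations = replicates), then adjusts the p-values across
#' all genes by Benjamini-Hochberg.  Genes that are constant across all
#' observations get p = 1 (with a warning listing the count); genes with
#' zero within-group but positive between-group variance separate
#' perfectly and get p near 0.
#'
#' @param eset an [expr_set()].
#' @param design a [stage_design()]; every cell must have at least two
#'   replicates.
#' @param fdr_threshold adjusted-p cutoff in (0, 1).
#' @return data frame `gene, F, p, p_adj, selected`, attribute
#'   `fdr_threshold`.
#' @export
anova_de_filter <- function(eset, design, fdr_threshold = 1e-3) {
  stopifnot(inherits(eset, "expr_set"), inherits(design, "stage_design"),
            is_number(fdr_threshold), fdr_threshold > 0, fdr_threshold < 1)
  ann <- eset$annotations
  cells <- paste(design$condition, design$day, sep = "@")
  ann_cells <- paste(ann$condition, ann$day, sep = "@")
  missing <- setdiff(cells, ann_cells)
  if (length(missing)) {
    stop("design cells absent from the data: ",
         paste(missing, collapse = ", "))
  }
  keep <- ann_cells %in% cells
  g <- factor(ann_cells[keep], levels = cells)
  counts <- table(g)
  if (any(counts < 2L)) {
    stop("every stage time point needs >= 2 replicates; short cells: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  Y <- eset$values[, keep, drop = FALSE]
  N <- ncol(Y)
  G <- nlevels(g)
  ind <- stats::model.matrix(~ g - 1L)
  means_g <- Y %*% sweep(ind, 2L, colSums(ind), "/")
  grand <- rowMeans(Y)
  ssb <- rowSums(sweep((means_g - grand)^2, 2L, as.numeric(counts), "*"))
  ssw <- rowSums((Y - means_g[, as.integer(g), drop = FALSE])^2)
  Fstat <- (ssb / (G - 1L)) / (ssw / (N - G))
  p <- stats::pf(Fstat, G - 1L, N - G, lower.tail = FALSE)
  tol <- 1e-12 * pmax(1, rowMeans(Y * Y))
  constant <- (ssb + ssw) < tol
  if (any(constant)) {
    warning(sum(constant), " constant gene(s) assigned p = 1")
    Fstat[constant] <- 0
    p[constant] <- 1
  }
  sep <- !constant & ssw < tol # perfect separation
  p[sep] <- 0
  Fstat[sep] <- Inf
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(Y), F = Fstat, p = p, p_adj = p_adj,
                    selected = p_adj < fdr_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}

#' Subtract the day-0 baseline within each condition
#'
#' Optional control normalization: for each gene and condition, subtracts
#' the mean of that condition's day-0 samples, so profiles are expressed
#' relative to the undifferentiated starting state.  Off by default in
#' [run_pipeline()].
#'
#' @param eset an [expr_set()] whose every condition includes day 0.
#' @return the adjusted [expr_set()].
#' @export
subtract_baseline <- function(eset) {
  stopifnot(inherits(eset, "expr_set"))
  ann <- eset$annotations
  for (cond in unique(ann$condition)) {
    base_cols <- ann$condition == cond & ann$day == 0
    if (!any(base_cols)) stop("condition '", cond, "' has no day-0 samples")
    base <- rowMeans(eset$values[, base_cols, drop = FALSE])
    cols <- ann$condition == cond
    eset$values[, cols] <- eset$values[, cols, drop = FALSE] - base
  }
  eset
}

#' Collapse probe-level rows to gene level by maximum variance
#'
#' Utility for probe-level input: keeps, for each gene, the probe with
#' the largest variance across samples.
#'
#' @param values probes x samples matrix with probe rownames.
#' @param probe_gene named character vector mapping probe -> gene.
#' @return genes x samples matrix.
#' @export
collapse_probes <- function(values, probe_gene) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  probe_gene <- probe_gene[rownames(values)]
  if (anyNA(probe_gene)) stop("all probes must have a gene mapping")
  v <- apply(values, 1L, stats::var)
  keep <- unlist(lapply(split(seq_len(nrow(values)), probe_gene),
                        function(ix) ix[which.max(v[ix])]))
  out <- values[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  out
}
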