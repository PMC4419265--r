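#' Interpolated series length for a target regression
#'
#' The regression for a target with `Q` candidate neighbours estimates
#' `Q + 2` parameters (interaction activities, translation effect,
#' degradation); the series is interpolated so the number of data points
#' is roughly 3--5 times that count.
#'
#' @param Q number of candidate neighbours.
#' @param multiplier data-to-parameter ratio in `[3, 5]`; default 4.
#' @return integer `ceiling(multiplier * (Q + 2))`.
#' @export
choose_L <- function(Q, multiplier = 4) {
  stopifnot(is_count(Q, 0L), is_number(multiplier),
            multiplier >= 3, multiplier <= 5)
  as.integer(ceiling(multiplier * (Q + 2L)))
}

#' Interpolate a stage profile to L evenly spaced pseudo-times
#'
#' Fits a natural cubic spline through each gene's (day, value) knots and
#' evaluates it at `L` points evenly spaced over the day range.  Knot
#' values are reproduced exactly when a pseudo-time coincides with a
#' knot.  The attached mRNA series, if any, is interpolated on the same
#' grid.
#'
#' @param profile a [stage_profile()] with at least 4 time points.
#' @param L target number of points, `>=` the original count.
#' @return a [stage_profile()] on the pseudo-time grid.
#' @export
interpolate_profile <- function(profile, L) {
  stopifnot(inherits(profile, "stage_profile"), is_count(L, 2L))
  n0 <- length(profile$days)
  if (n0 < 4L) stop("cubic spline interpolation needs >= 4 time points")
  if (L < n0) stop("L (", L, ") must be >= the number of original points (",
                   n0, ")")
  grid <- seq(profile$days[1L], profile$days[n0], length.out = L)
  interp <- function(mat) {
    t(apply(mat, 1L, function(y) {
      stats::spline(profile$days, y, xout = grid, method = "natural")$y
    }))
  }
  stage_profile(profile$stage, profile$genes, grid, interp(profile$values),
                mrna = if (!is.null(profile$mrna)) interp(profile$mrna))
}

#' Per-target regression problem for the bilinear interaction model
#'
#' Builds the least-squares system for one target protein `p`: responses
#' `z_p[t+1]` against columns `z_p[t] z_q[t]` for each candidate
#' neighbour `q`, an mRNA column `x_p[t]` and the autoregressive column
#' `z_p[t]` (coefficient `1 - beta_p`).  With `L` interpolated points the
#' system has `L - 1` rows.  When no distinct mRNA series is available
#' (`x` absent), the `x_p` and `z_p` columns of the model would be
#' numerically identical, so they are merged into the single `z_p` column
#' whose coefficient absorbs `1 + alpha - beta`; the fit then reports
#' `alpha = 0` and `beta` from that combined coefficient.
#'
#' @param z genes x L numeric matrix (interpolated protein series) with
#'   gene rownames, or a [stage_profile()] (its `mrna` matrix, if
#'   present, supplies `x`).
#' @param target target gene name.
#' @param neighbors candidate neighbour gene names (may be empty).
#' @param x optional genes x L matrix of a distinct mRNA series.
#' @return an object of class `regression_problem`.
#' @export
regression_problem <- function(z, target, neighbors, x = NULL) {
  if (inherits(z, "stage_profile")) {
    x <- x %||% z$mrna
    z <- z$values
  }
  stopifnot(is.matrix(z), !is.null(rownames(z)))
  L <- ncol(z)
  if (L < 3L) stop("need at least 3 time points")
  if (!target %in% rownames(z)) stop("target '", target, "' not in profile")
  neighbors <- as.character(neighbors)
  if (!all(neighbors %in% rownames(z))) {
    stop("neighbors missing from profile: ",
         paste(setdiff(neighbors, rownames(z)), collapse = ", "))
  }
  neighbors <- sort(neighbors)
  tt <- seq_len(L - 1L)
  zp <- z[target, tt]
  y <- z[target, tt + 1L]
  inter <- if (length(neighbors)) {
    m <- t(z[neighbors, tt, drop = FALSE] * rep(zp, each = length(neighbors)))
    colnames(m) <- neighbors
    m
  } else {
    matrix(0, length(tt), 0L)
  }
  has_mrna <- !is.null(x)
  base <- if (has_mrna) {
    cbind(x = x[target, tt], z = zp)
  } else {
    cbind(z = zp)
  }
  structure(list(target = target, neighbors = neighbors, y = y,
                 interactions = inter, base = base, L = L,
                 n_obs = length(tt), has_mrna = has_mrna),
            class = "regression_problem")
}

#' Akaike information criterion for a least-squares fit
#'
#' `AIC = n * log(rss / n) + 2k` with the residual sum of squares floored
#' at `n` times machine epsilon so that exact fits stay finite and subset
#' comparisons at numerically zero residual are decided by the parameter
#' penalty alone.  The small-sample variant adds the AICc correction
#' `2k(k+1)/(n-k-1)`.
#'
#' @param rss residual sum of squares, `>= 0`.
#' @param n number of observations (regression rows).
#' @param k number of estimated parameters.
#' @param variant `"aic"` (default) or `"aicc"`.
#' @return the criterion value.
#' @export
aic_score <- function(rss, n, k, variant = c("aic", "aicc")) {
  variant <- match.arg(variant)
  stopifnot(is_number(rss), rss >= 0, is_count(n, 1L), is_count(k, 0L))
  rss_eff <- max(rss, n * .Machine$double.eps)
  out <- n * log(rss_eff / n) + 2 * k
  if (variant == "aicc") {
    out <- out + if (n - k - 1L > 0L) 2 * k * (k + 1L) / (n - k - 1L) else Inf
  }
  out
}

# Least-squares fit of a column subset; returns NULL if rank deficient.
fit_subset <- function(problem, idx, variant = "aic") {
  Phi <- cbind(problem$interactions[, idx, drop = FALSE], problem$base)
  dec <- qr(Phi)
  if (dec$rank < ncol(Phi)) return(NULL)
  coef <- qr.coef(dec, problem$y)
  resid <- problem$y - as.numeric(Phi %*% coef)
  rss <- sum(resid^2)
  k <- ncol(Phi)
  list(idx = idx, coef = coef, rss = rss, k = k,
       aic = aic_score(rss, problem$n_obs, k, variant))
}

as_target_fit <- function(problem, sub, strategy, n_skipped = 0L) {
  nb <- problem$neighbors[sub$idx]
  b <- stats::setNames(sub$coef[seq_along(nb)], nb)
  base_coef <- sub$coef[length(sub$idx) + seq_len(ncol(problem$base))]
  if (problem$has_mrna) {
    alpha <- unname(base_coef[1L])
    beta <- 1 - unname(base_coef[2L])
  } else {
    alpha <- 0 # merged column: coefficient absorbs 1 + alpha - beta
    beta <- 1 - unname(base_coef[1L])
  }
  structure(list(target = problem$target, candidates = problem$neighbors,
                 retained = nb, b = b, alpha = alpha, beta = beta,
                 rss = sub$rss, aic = sub$aic, k = sub$k,
                 n_obs = problem$n_obs, L = problem$L,
                 has_mrna = problem$has_mrna, strategy = strategy,
                 n_skipped = n_skipped),
            class = "target_fit")
}

#' @export
print.target_fit <- function(x, ...) {
  cat("target_fit '", x$target, "': ", length(x$retained), "/",
      length(x$candidates), " interactions retained (", x$strategy,
      "), alpha=", signif(x$alpha, 4), ", beta=", signif(x$beta, 4),
      ", AIC=", signif(x$aic, 6), "\n", sep = "")
  invisible(x)
}

#' Ordinary least-squares fit of the full candidate model
#'
#' Solves the least-squares problem for all candidate columns, without
#' pruning.  Rank-deficient designs (e.g. duplicated neighbour series)
#' are an error.
#'
#' @param problem a [regression_problem()].
#' @param variant AIC variant for the reported score.
#' @return an object of class `target_fit` with elements `b` (named
#'   activities), `alpha`, `beta`, `rss`, `aic`, `retained`.
#' @export
fit_target <- function(problem, variant = "aic") {
  stopifnot(inherits(problem, "regression_problem"))
  sub <- fit_subset(problem, seq_along(problem$neighbors), variant)
  if (is.null(sub)) {
    stop("rank-deficient design for target '", problem$target,
         "' (collinear neighbors)")
  }
  as_target_fit(problem, sub, strategy = "full")
}

# Pick the best candidate among fitted subsets: minimum AIC, ties broken
# toward the smaller model, then lexicographic neighbour order.
select_best <- function(subs, tol = 1e-9) {
  aics <- vapply(subs, `[[`, numeric(1L), "aic")
  sizes <- lengths(lapply(subs, `[[`, "idx"))
  keys <- vapply(subs, function(s) paste(sprintf("%06d", s$idx),
                                         collapse = ","), character(1L))
  cand <- which(aics <= min(aics) + tol)
  cand[order(sizes[cand], keys[cand])][1L]
}

#' Prune candidate interactions by AIC
#'
#' Searches over subsets of the candidate interactions (the translation
#' and degradation terms are always kept) for the minimum-AIC model.
#' With `Q <= exhaustive_limit` candidates all `2^Q` subsets are
#' evaluated; otherwise greedy backward elimination starts from the full
#' model and repeatedly removes the single interaction whose removal
#' most decreases the AIC, stopping when no removal decreases it.  Ties
#' are broken toward the smaller model, then by lexicographic neighbour
#' order.  Subsets whose design is rank deficient are skipped and
#' counted.
#'
#' @param problem a [regression_problem()].
#' @param strategy `"auto"` (default), `"exhaustive"` or `"greedy"`.
#' @param exhaustive_limit largest `Q` for which `"auto"` enumerates
#'   subsets exhaustively.
#' @param variant AIC variant, see [aic_score()].
#' @return a `target_fit` for the selected model.
#' @export
prune_by_aic <- function(problem, strategy = c("auto", "exhaustive",
                                               "greedy"),
                         exhaustive_limit = 8L, variant = "aic") {
  stopifnot(inherits(problem, "regression_problem"),
            is_count(exhaustive_limit, 0L))
  strategy <- match.arg(strategy)
  Q <- length(problem$neighbors)
  if (Q == 0L) {
    return(fit_target(problem, variant))
  }
  if (strategy == "auto") {
    strategy <- if (Q <= exhaustive_limit) "exhaustive" else "greedy"
  }
  n_skipped <- 0L
  if (strategy == "exhaustive") {
    subs <- vector("list", 2^Q)
    m <- 0L
    bits <- 2^(seq_len(Q) - 1L)
    for (mask in 0:(2^Q - 1L)) {
      idx <- which(bitwAnd(mask, bits) > 0)
      s <- fit_subset(problem, idx, variant)
      if (is.null(s)) {
        n_skipped <- n_skipped + 1L
        next
      }
      m <- m + 1L
      subs[[m]] <- s
    }
    subs <- subs[seq_len(m)]
    if (!m) stop("all candidate subsets rank deficient for target '",
                 problem$target, "'")
    if (n_skipped) {
      message(n_skipped, " rank-deficient subset(s) skipped for target '",
              problem$target, "'")
    }
    return(as_target_fit(problem, subs[[select_best(subs)]],
                         strategy = "exhaustive", n_skipped = n_skipped))
  }
  # Greedy backward elimination with refit after each removal.
  current <- fit_subset(problem, seq_len(Q), variant)
  if (is.null(current)) {
    stop("rank-deficient design for target '", problem$target,
         "' (collinear neighbors)")
  }
  repeat {
    if (!length(current$idx)) break
    trials <- lapply(seq_along(current$idx), function(j) {
      fit_subset(problem, current$idx[-j], variant)
    })
    ok <- !vapply(trials, is.null, logical(1L))
    n_skipped <- n_skipped + sum(!ok)
    trials <- trials[ok]
    if (!length(trials)) break
    best <- trials[[select_best(trials)]]
    if (best$aic < current$aic) current <- best else break
  }
  as_target_fit(problem, current, strategy = "greedy",
                n_skipped = n_skipped)
}

#' Fitting configuration for stage network construction
#'
#' @param L explicit number of interpolation points shared by all
#'   targets; `NULL` (default) uses
#'   `max(n_timepoints, choose_L(max Q, L_multiplier))`.
#' @param L_multiplier data-to-parameter ratio passed to [choose_L()].
#' @param strategy,exhaustive_limit,variant pruning options, see
#'   [prune_by_aic()] and [aic_score()].
#' @param symmetrize average the fitted activity matrix with its
#'   transpose (default `FALSE`: the per-target estimates are kept
#'   asymmetric as fitted).
#' @param b_floor magnitude below which retained activities are set to
#'   zero (numerical noise floor for degree counting).
#' @return list of class `net_config`.
#' @export
net_config <- function(L = NULL, L_multiplier = 4, strategy = "auto",
                       exhaustive_limit = 8L, variant = "aic",
                       symmetrize = FALSE, b_floor = 1e-12) {
  stopifnot(is.null(L) || is_count(L, 4L), is_number(L_multiplier),
            L_multiplier >= 3, L_multiplier <= 5,
            is_count(exhaustive_limit, 0L), is.logical(symmetrize),
            is_number(b_floor), b_floor >= 0)
  structure(list(L = L, L_multiplier = L_multiplier, strategy = strategy,
                 exhaustive_limit = as.integer(exhaustive_limit),
                 variant = variant, symmetrize = symmetrize,
                 b_floor = b_floor),
            class = "net_config")
}

#' Construct the dynamic interaction network of one stage
#'
#' Restricts the candidate edges to the profile's gene set, interpolates
#' the profile to a shared pseudo-time grid, and for every gene fits and
#' AIC-prunes the per-target regression; surviving interaction activities
#' are assembled into a sparse stage matrix.  Genes whose fit fails
#' (rank-deficient design) are recorded as isolated.
#'
#' @param profile a [stage_profile()]; if it carries an `mrna` matrix the
#'   full model with separate translation column is fitted.
#' @param candidates data frame of undirected candidate edges with
#'   columns `source`, `target`.
#' @param config a [net_config()].
#' @return an object of class `stage_network`: list with `stage`,
#'   `genes`, `b` (sparse activity matrix, rows = targets), `fits`
#'   (per-gene summary data frame), `failed`, `L`, `config`.
#' @export
construct_stage_network <- function(profile, candidates,
                                    config = net_config()) {
  stopifnot(inherits(profile, "stage_profile"), inherits(config, "net_config"))
  genes <- profile$genes
  if (!length(genes)) stop("profile gene set is empty")
  candidates <- as.data.frame(candidates)
  stopifnot(all(c("source", "target") %in% names(candidates)))
  keep <- candidates$source %in% genes & candidates$target %in% genes &
    candidates$source != candidates$target
  candidates <- candidates[keep, c("source", "target")]
  if (!nrow(candidates)) {
    warning("no candidate edges within the profile gene set; ",
            "returning an empty network")
  }
  nbrs <- lapply(stats::setNames(genes, genes), function(g) {
    sort(unique(c(candidates$target[candidates$source == g],
                  candidates$source[candidates$target == g])))
  })
  q_max <- max(lengths(nbrs), 0L)
  L <- config$L %||% max(length(profile$days),
                         choose_L(q_max, config$L_multiplier))
  interp <- interpolate_profile(profile, L)
  fits <- vector("list", length(genes))
  failed <- character(0)
  rows <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]
    fit <- tryCatch({
      prob <- regression_problem(interp, g, nbrs[[g]])
      prune_by_aic(prob, strategy = config$strategy,
                   exhaustive_limit = config$exhaustive_limit,
                   variant = config$variant)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      failed <- c(failed, g)
      message("target '", g, "' dropped: ", conditionMessage(fit))
      fits[[i]] <- data.frame(gene = g, Q = length(nbrs[[g]]),
                              n_retained = NA_integer_, alpha = NA_real_,
                              beta = NA_real_, rss = NA_real_,
                              aic = NA_real_, status = "failed",
                              stringsAsFactors = FALSE)
      next
    }
    b <- fit$b[abs(fit$b) > config$b_floor]
    if (length(b)) {
      rows[[g]] <- data.frame(source = g, target = names(b),
                              b = unname(b), stringsAsFactors = FALSE)
    }
    fits[[i]] <- data.frame(gene = g, Q = length(nbrs[[g]]),
                            n_retained = length(b), alpha = fit$alpha,
                            beta = fit$beta, rss = fit$rss, aic = fit$aic,
                            status = "ok", stringsAsFactors = FALSE)
  }
  edge_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(0), target = character(0),
               b = numeric(0), stringsAsFactors = FALSE)
  B <- Matrix::sparseMatrix(
    i = match(edge_df$source, genes), j = match(edge_df$target, genes),
    x = edge_df$b, dims = c(length(genes), length(genes)),
    dimnames = list(genes, genes))
  if (config$symmetrize) B <- (B + Matrix::t(B)) / 2
  structure(list(stage = profile$stage, genes = genes, b = B,
                 fits = do.call(rbind, fits), failed = failed, L = L,
                 config = config),
            class = "stage_network")
}

#' Build a stage network directly from an edge list
#'
#' Low-level constructor used by readers and tests; entries are placed as
#' given (rows = source/target protein of the regression).
#'
#' @param genes gene universe of the network.
#' @param edges data frame `source, target, b`.
#' @param stage stage label.
#' @return a `stage_network`.
#' @export
stage_network_from_edges <- function(genes, edges, stage) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("source", "target", "b") %in% names(edges)),
            all(edges$source %in% genes), all(edges$target %in% genes))
  B <- Matrix::sparseMatrix(
    i = match(edges$source, genes), j = match(edges$target, genes),
    x = edges$b, dims = c(length(genes), length(genes)),
    dimnames = list(genes, genes))
  structure(list(stage = stage, genes = genes, b = B, fits = NULL,
                 failed = character(0), L = NA_integer_,
                 config = NULL),
            class = "stage_network")
}

#' @export
print.stage_network <- function(x, ...) {
  cat("stage_network '", x$stage, "': ", length(x$genes), " genes, ",
      Matrix::nnzero(x$b), " directed interaction entries",
      if (length(x$failed)) paste0(" (", length(x$failed), " failed)"),
      "\n", sep = "")
  invisible(x)
}

#' Edge data frame of a stage network
#'
#' @param net a `stage_network`.
#' @return data frame `source, target, b, stage` (nonzero entries only).
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "stage_network"))
  s <- Matrix::summary(net$b)
  out <- data.frame(source = net$genes[s$i], target = net$genes[s$j],
                    b = s$x, stage = rep(net$stage, length(s$x)),
                    stringsAsFactors = FALSE)
  out <- out[abs(out$b) > 0, , drop = FALSE]
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Undirected edge recovery against a ground truth
#'
#' Compares the fitted network to a [ground_truth()] stage: an undirected
#' pair is called recovered when the interaction was retained in both
#' target regressions (`p` as target and `q` as target), the consensus
#' rule that guards against AIC's per-regression false-retention rate.
#' `rule = "either"` relaxes this to a single direction.
#'
#' @param net a fitted `stage_network`.
#' @param truth a [ground_truth()].
#' @param stage stage label to compare against.
#' @param rule `"both"` (default) or `"either"`.
#' @param b_floor activity magnitude regarded as zero.
#' @return list with `precision`, `recall`, `f1`, `n_true`, `n_called`.
#' @export
edge_recovery_stats <- function(net, truth, stage, rule = c("both", "either"),
                                b_floor = 1e-12) {
  rule <- match.arg(rule)
  stopifnot(inherits(net, "stage_network"), inherits(truth, "ground_truth"))
  Bt <- truth$stage_networks[[stage]]
  st <- Matrix::summary(Bt)
  true_keys <- unique(pair_key(truth$genes[st$i], truth$genes[st$j])[
    abs(st$x) > 0])
  ed <- network_edges(net)
  ed <- ed[abs(ed$b) > b_floor, ]
  keys <- pair_key(ed$source, ed$target)
  tab <- table(keys)
  called <- if (rule == "both") names(tab)[tab >= 2L] else names(tab)
  tp <- sum(called %in% true_keys)
  list(precision = if (length(called)) tp / length(called) else NA_real_,
       recall = if (length(true_keys)) tp / length(true_keys) else NA_real_,
       f1 = if (length(called) && length(true_keys) && tp > 0)
         2 * tp / (length(called) + length(true_keys)) else 0,
       n_true = length(true_keys), n_called = length(called))
}
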