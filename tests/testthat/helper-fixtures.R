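# Shared fixtures: small ground truths, profiles and independent oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small random truth with all parameter draws reproducible from `seed`.
small_truth <- function(n_genes = 12L, n_edges = 14L, noise_sd = 0,
                        seed = 1L) {
  ground_truth(n_genes = n_genes, n_true_edges = n_edges,
               noise_sd = noise_sd, seed = seed)
}

# A truth whose dynamics are fully controlled by hand: no interactions,
# no translation, no degradation unless overridden afterwards.
null_truth <- function(n_genes = 3L, seed = 1L) {
  tr <- ground_truth(n_genes = n_genes, n_true_edges = 1L, noise_sd = 0,
                     seed = seed)
  zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(n_genes, n_genes),
                               dimnames = list(tr$genes, tr$genes))
  tr$stage_networks <- lapply(tr$stage_networks, function(B) zero)
  tr$alpha[] <- 0
  tr$beta[] <- 0
  tr
}

# Independent oracle: direct re-substitution of the recurrence.
recurrence_oracle <- function(truth, stage, z0, x, n_steps) {
  B <- as.matrix(truth$stage_networks[[stage]])
  n <- length(truth$genes)
  Z <- matrix(NA_real_, n, n_steps + 1L)
  Z[, 1L] <- z0
  for (t in seq_len(n_steps)) {
    zt <- Z[, t]
    for (p in seq_len(n)) {
      Z[p, t + 1L] <- zt[p] + sum(B[p, ] * zt[p] * zt) +
        truth$alpha[p] * x[p, t] - truth$beta[p] * zt[p]
    }
  }
  rownames(Z) <- truth$genes
  Z
}

# Independent brute-force relevance scores from a dense difference matrix.
brute_rs <- function(Dmat) {
  vapply(seq_len(nrow(Dmat)), function(p) {
    row <- Dmat[p, ]
    deg <- sum(row != 0)
    if (deg == 0) 0 else sum(abs(row)) / deg
  }, numeric(1L))
}

# Build an idn object from two dense activity matrices over shared genes.
idn_from_matrices <- function(B1, B2, genes = NULL) {
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(B1)))
  dimnames(B1) <- dimnames(B2) <- list(genes, genes)
  to_edges <- function(B) {
    ix <- which(B != 0, arr.ind = TRUE)
    data.frame(source = genes[ix[, 1]], target = genes[ix[, 2]],
               b = B[ix], stringsAsFactors = FALSE)
  }
  compute_idn(stage_network_from_edges(genes, to_edges(B1), "s1"),
              stage_network_from_edges(genes, to_edges(B2), "s2"))
}

# Random sparse activity matrix (dense storage) for RS property checks.
random_activity <- function(n, density = 0.3) {
  B <- matrix(0, n, n)
  mask <- matrix(stats::runif(n * n) < density, n, n)
  diag(mask) <- FALSE
  B[mask] <- stats::rnorm(sum(mask))
  B
}

# Tiny expression set: one condition, `days` x `reps`, values supplied
# per gene as a function(day) or a matrix.
toy_eset <- function(n_genes = 5L, days = c(0, 1, 3, 5, 7, 11, 13),
                     reps = 3L, value_fun = NULL, noise = 0,
                     condition = "LSB", seed = 1L) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    cols <- list()
    ann <- list()
    for (d in days) {
      for (r in seq_len(reps)) {
        base <- if (is.null(value_fun)) rep(0, n_genes) else value_fun(d)
        id <- sprintf("%s_d%d_r%d", gsub("[^A-Za-z0-9]+", ".", condition),
                      d, r)
        cols[[id]] <- base + stats::rnorm(n_genes, 0, noise)
        ann[[id]] <- data.frame(sampleID = id, condition = condition,
                                day = d, replicate = r)
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- genes
    expr_set(values, do.call(rbind, ann))
  })
}
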