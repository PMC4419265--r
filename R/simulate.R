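#' Ground truth for simulating stage-specific interaction dynamics
#'
#' Draws a random ground truth for the bilinear interaction model
#' \deqn{z_p[t+1] = z_p[t] + \sum_q b_{pq} z_p[t] z_q[t] + \alpha_p x_p[t]
#'   - \beta_p z_p[t] + \omega_p[t+1],}
#' where `z_p` is the abundance of protein `p`, `b_pq` the interaction
#' activity between `p` and `q`, `x_p` its mRNA input, `alpha_p` the
#' translation effect, `beta_p` the per-step degradation rate and
#' `omega_p` process noise.  A set of undirected true edges is sampled;
#' each edge is present (with a stage-specific signed activity) in a
#' random subset of the three stages, so that edges emerge, diminish and
#' change strength across stages.  Activities are symmetric
#' (`b_pq = b_qp`) within a stage.
#'
#' Interaction activities are drawn with magnitude in `b_range` and then
#' passed through a stability guard: the bilinear recurrence is unstable
#' whenever a gene's total incident interaction load
#' `sum_q |b_pq| * z_q` rivals its degradation rate, so incident
#' activities of overloaded genes are rescaled (symmetrically, per
#' stage) until the load stays below `guard_margin * beta_p` with every
#' neighbour evaluated at its self-consistent peak abundance
#' (`2.2 *` its baseline: the drive peak plus feedback headroom).
#' Degradation is drawn from the upper part of the admissible range and
#' the translation effect is tied to it
#' (`alpha = beta * U(alpha_tracking)`), so protein levels track the
#' mRNA drive with DC gain near 1 and the trajectory neither decays to
#' zero nor drifts away from the baseline scale.
#'
#' Each gene receives a smooth deterministic mRNA drive (a mixture of
#' three low-frequency sinusoids around its baseline) used by
#' [simulate_stage_profile()] and [generate_dataset()]; a persistently
#' exciting exogenous input of large relative amplitude is what makes
#' the kinetic parameters identifiable from a single trajectory.
#'
#' @param n_genes number of genes.
#' @param n_true_edges number of undirected true interactions.
#' @param stages stage labels; exactly three.
#' @param b_range magnitude range for interaction activities (before the
#'   stability guard).
#' @param alpha_tracking range of the ratio `alpha / beta`.
#' @param beta_range range for degradation rates (within `[0, 1]`).
#' @param baseline_range range for baseline abundances `z_p[0]`.
#' @param noise_sd standard deviation of the process noise `omega`.
#' @param presence_prob probability that a true edge is active in a given
#'   stage (edges inactive everywhere are reassigned to one random stage).
#' @param guard_margin fraction of `beta_p` the peak interaction load may
#'   reach.
#' @param seed integer seed; all draws are reproducible.
#' @return An object of class `ground_truth`: a list with elements
#'   `genes`, `stages`, `stage_networks` (named list of sparse symmetric
#'   activity matrices), `alpha`, `beta`, `baseline`, `noise_sd`,
#'   `edges` (data frame with one activity column per stage),
#'   `candidate_edges`, `drive` (mRNA drive coefficients) and `seed`.
#' @seealso [simulate_dynamics()], [generate_dataset()],
#'   [generate_candidate_network()]
#' @export
ground_truth <- function(n_genes = 30L, n_true_edges = 40L,
                         stages = c("I", "II", "III"),
                         b_range = c(0.001, 0.05),
                         alpha_tracking = c(0.8, 1.2),
                         beta_range = c(0.4, 0.5),
                         baseline_range = c(2.5, 3.5),
                         noise_sd = 0.05,
                         presence_prob = 0.7,
                         guard_margin = 0.5,
                         seed = 1L) {
  stopifnot(is_count(n_genes, 2L), is_count(n_true_edges, 1L),
            length(stages) == 3L, !anyDuplicated(stages),
            is_number(noise_sd), noise_sd >= 0,
            beta_range[1] >= 0, beta_range[2] <= 1,
            presence_prob > 0, presence_prob <= 1)
  n_pairs <- choose(n_genes, 2L)
  if (n_true_edges > n_pairs) {
    stop("n_true_edges exceeds the number of available gene pairs (",
         n_pairs, ")")
  }
  genes <- sprintf("G%03d", seq_len(n_genes))
  with_seed(seed, {
    idx_mat <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
    sel <- idx_mat[sort(sample.int(nrow(idx_mat), n_true_edges)), ,
                   drop = FALSE]
    presence <- matrix(stats::runif(n_true_edges * 3L) < presence_prob,
                       n_true_edges, 3L)
    none <- which(rowSums(presence) == 0L)
    for (i in none) presence[i, sample.int(3L, 1L)] <- TRUE
    b_vals <- matrix(
      sample(c(-1, 1), n_true_edges * 3L, replace = TRUE) *
        stats::runif(n_true_edges * 3L, b_range[1], b_range[2]),
      n_true_edges, 3L)
    b_vals[!presence] <- 0
    beta <- stats::setNames(
      stats::runif(n_genes, beta_range[1], beta_range[2]), genes)
    baseline <- stats::setNames(
      stats::runif(n_genes, baseline_range[1], baseline_range[2]), genes)
    # Stability guard: cap each gene's incident interaction load (per
    # stage) at guard_margin * beta_p with neighbours at their peak
    # abundance; symmetric rescale so b_pq = b_qp is preserved.
    z_peak <- 2.2 * baseline
    for (s in seq_len(3L)) {
      load <- rep(0, n_genes)
      contrib <- abs(b_vals[, s]) # load on p counts |b_pq| * peak(z_q)
      load_add <- tapply(c(contrib * z_peak[sel[, 2L]],
                           contrib * z_peak[sel[, 1L]]),
                         c(sel[, 1L], sel[, 2L]), sum)
      load[as.integer(names(load_add))] <- load_add
      s_gene <- pmin(1, guard_margin * beta / pmax(load, 1e-12))
      b_vals[, s] <- b_vals[, s] * pmin(s_gene[sel[, 1L]], s_gene[sel[, 2L]])
    }
    stage_networks <- lapply(seq_len(3L), function(s) {
      Matrix::sparseMatrix(
        i = c(sel[, 1L], sel[, 2L]), j = c(sel[, 2L], sel[, 1L]),
        x = rep(b_vals[, s], 2L), dims = c(n_genes, n_genes),
        dimnames = list(genes, genes))
    })
    names(stage_networks) <- stages
    edges <- data.frame(source = genes[sel[, 1L]], target = genes[sel[, 2L]],
                        stringsAsFactors = FALSE)
    for (s in seq_len(3L)) edges[[paste0("b_", stages[s])]] <- b_vals[, s]
    amp <- matrix(stats::runif(n_genes * 3L, 0.1, 0.3), n_genes, 3L,
                  dimnames = list(genes, NULL))
    amp_tot <- rowSums(amp)
    amp <- amp * pmin(1, 0.8 / amp_tot) # keep the drive positive
    truth <- list(
      genes = genes,
      stages = stages,
      stage_networks = stage_networks,
      alpha = beta * stats::runif(n_genes, alpha_tracking[1],
                                  alpha_tracking[2]),
      beta = beta,
      baseline = baseline,
      noise_sd = noise_sd,
      edges = edges,
      candidate_edges = edges[, c("source", "target")],
      drive = list(
        amp = amp,
        period = matrix(stats::runif(n_genes * 3L, 8, 40), n_genes, 3L,
                        dimnames = list(genes, NULL)),
        phase = matrix(stats::runif(n_genes * 3L, 0, 2 * pi), n_genes, 3L,
                       dimnames = list(genes, NULL))),
      seed = as.integer(seed))
    class(truth) <- "ground_truth"
    truth
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", length(x$genes), "genes,", nrow(x$edges),
      "true undirected edges, stages", paste(x$stages, collapse = ", "),
      "\n  process noise sd:", x$noise_sd, " seed:", x$seed, "\n")
  invisible(x)
}

#' Deterministic mRNA drive series
#'
#' Evaluates each gene's smooth exogenous mRNA input at the requested
#' times: the gene baseline modulated by three sinusoids whose
#' amplitudes, periods and phases were drawn once in [ground_truth()].
#'
#' @param truth a [ground_truth()] object.
#' @param times numeric vector of time points (in unit steps).
#' @return genes x times matrix, strictly positive.
#' @export
mrna_drive <- function(truth, times) {
  stopifnot(inherits(truth, "ground_truth"), is.numeric(times))
  d <- truth$drive
  n <- length(truth$genes)
  out <- matrix(1, n, length(times),
                dimnames = list(truth$genes, paste0("t", times)))
  for (j in 1:3) {
    out <- out + d$amp[, j] *
      sin(outer(2 * pi / d$period[, j], times) + d$phase[, j])
  }
  out * truth$baseline
}

# One transition of the bilinear recurrence; B indexes target rows.
step_bilinear <- function(B, zt, alpha, beta, xt, eps) {
  zt + zt * as.numeric(B %*% zt) + alpha * xt - beta * zt + eps
}

# Simulate a trajectory under a per-step stage schedule.  `x` is either a
# genes x n_steps matrix of exogenous inputs or NULL for the
# self-referential noiseless latent convention (x_p[t] := z_p[t]).
# `eps` is a genes x n_steps matrix of process-noise draws (or NULL).
sim_path <- function(truth, schedule, z0, x = NULL, eps = NULL) {
  n <- length(truth$genes)
  n_steps <- length(schedule)
  Z <- matrix(NA_real_, n, n_steps + 1L,
              dimnames = list(truth$genes, paste0("t", 0:n_steps)))
  Z[, 1L] <- z0
  for (t in seq_len(n_steps)) {
    zt <- Z[, t]
    B <- truth$stage_networks[[schedule[t]]]
    xt <- if (is.null(x)) zt else x[, t]
    et <- if (is.null(eps)) 0 else eps[, t]
    znext <- step_bilinear(B, zt, truth$alpha, truth$beta, xt, et)
    if (any(!is.finite(znext)) || max(abs(znext)) > 1e8) {
      bad <- which(!is.finite(znext) | abs(znext) > 1e8)[1L]
      stop("trajectory diverged at step ", t, " for gene ",
           truth$genes[bad], call. = FALSE)
    }
    Z[, t + 1L] <- znext
  }
  Z
}

#' Simulate protein dynamics for one stage
#'
#' Iterates the bilinear recurrence for `n_steps` unit steps under a
#' single stage's interaction matrix.  The mRNA input `x` defaults to the
#' noiseless latent trajectory (the deterministic solution of the
#' recurrence with `x_p[t] = z_p[t]`), so that the same series plays both
#' roles; supply `x = "drive"` to use the ground truth's exogenous mRNA
#' drive, or a genes x `n_steps` matrix of custom inputs.
#'
#' @param truth a [ground_truth()] object.
#' @param stage stage label, one of `truth$stages`.
#' @param n_steps number of transitions to simulate.
#' @param z0 per-gene initial abundance (default: the truth baselines).
#' @param x mRNA input: `NULL` (noiseless latent), `"drive"`, or a matrix
#'   with at least `n_steps` columns.
#' @param noise_sd process noise standard deviation (default: the truth's).
#' @param seed seed for the noise draws; required reproducibility handle
#'   when `noise_sd > 0`.
#' @return genes x (`n_steps` + 1) trajectory matrix, columns `t0..tn`.
#' @export
simulate_dynamics <- function(truth, stage, n_steps, z0 = truth$baseline,
                              x = NULL, noise_sd = truth$noise_sd,
                              seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), is_count(n_steps, 1L),
            is_number(noise_sd), noise_sd >= 0)
  if (!stage %in% names(truth$stage_networks)) {
    stop("unknown stage '", stage, "'; expected one of ",
         paste(names(truth$stage_networks), collapse = ", "))
  }
  if (!all(is.finite(z0))) stop("z0 must be finite")
  n <- length(truth$genes)
  if (identical(x, "drive")) {
    x <- mrna_drive(truth, 0:(n_steps - 1L))
  }
  if (!is.null(x)) {
    x <- as.matrix(x)
    if (nrow(x) != n || ncol(x) < n_steps) {
      stop("x must be a ", n, " x >=", n_steps, " matrix")
    }
  }
  eps <- NULL
  if (noise_sd > 0) {
    eps <- with_seed(seed,
                     matrix(stats::rnorm(n * n_steps, 0, noise_sd), n, n_steps))
  }
  schedule <- rep(stage, n_steps)
  if (is.null(x)) {
    # Latent convention: noiseless path with x := z, then (if noisy) the
    # latent series serves as the deterministic mRNA input.
    latent <- sim_path(truth, schedule, z0, x = NULL, eps = NULL)
    if (is.null(eps)) return(latent)
    x <- latent[, seq_len(n_steps), drop = FALSE]
  }
  sim_path(truth, schedule, z0, x = x, eps = eps)
}

#' Simulate a stage profile on the native unit-step grid
#'
#' Runs one stage's dynamics driven by the exogenous mRNA series and
#' packages the result as a [stage_profile()] whose days are the unit
#' steps `0..n_steps` and which carries the mRNA series alongside the
#' protein trajectory.  Profiles built this way support full recovery of
#' `b`, `alpha` and `beta` by [construct_stage_network()], because the
#' mRNA and protein regression columns are distinct.
#'
#' @inheritParams simulate_dynamics
#' @return a `stage_profile` with an `mrna` matrix attached.
#' @export
simulate_stage_profile <- function(truth, stage, n_steps,
                                   noise_sd = truth$noise_sd, seed = NULL) {
  x <- mrna_drive(truth, 0:n_steps)
  z <- simulate_dynamics(truth, stage, n_steps, x = x,
                         noise_sd = noise_sd, seed = seed)
  stage_profile(stage = stage, genes = truth$genes, days = 0:n_steps,
                values = z, mrna = x)
}

#' Sampling design emulating a three-condition differentiation time course
#'
#' Describes the measurement layout: three induction conditions sampled on
#' the same days with replicate arrays, and the day at which each
#' condition's dynamics switch to the next stage network (inducers are
#' added at day 0, day 1 and day 3 respectively).
#'
#' @param conditions three condition labels.
#' @param days sampled days; strictly increasing, starting at 0.
#' @param replicates replicate arrays per (condition, day) cell.
#' @param switch_days per-condition day at which each successive stage's
#'   dynamics take over; list of numeric vectors aligned with
#'   `conditions`, each starting at 0.
#' @return an object of class `simulated_design`.
#' @export
simulated_design <- function(conditions = c("LSB", "LSB/S/F8",
                                            "LSB/S/F8/CHIR"),
                             days = c(0, 1, 3, 5, 7, 11, 13),
                             replicates = 3L,
                             switch_days = list(0, c(0, 1), c(0, 1, 3))) {
  stopifnot(length(conditions) == 3L, !anyDuplicated(conditions),
            is.numeric(days), length(days) >= 2L, days[1] == 0,
            all(diff(days) > 0), is_count(replicates, 1L),
            length(switch_days) == 3L)
  structure(list(conditions = conditions, days = days,
                 replicates = as.integer(replicates),
                 switch_days = switch_days),
            class = "simulated_design")
}

# Stage label governing each unit-step transition t-1 -> t for a condition.
condition_schedule <- function(truth, design, cond_index, n_steps) {
  sw <- design$switch_days[[cond_index]]
  stages <- truth$stages[seq_along(sw)]
  vapply(seq_len(n_steps) - 1L, function(t0) {
    stages[max(which(sw <= t0))]
  }, character(1L))
}

#' Generate a simulated expression data set
#'
#' Simulates each condition's trajectory over the full day range with the
#' stage networks switching at the design's switch days, then samples the
#' design's (condition, day, replicate) cells, adding independent
#' Gaussian observation noise to each replicate.  The mRNA drive is the
#' deterministic input; process noise is drawn per condition.
#'
#' @param truth a [ground_truth()] object.
#' @param design a [simulated_design()].
#' @param obs_noise_sd replicate-level observation noise sd.
#' @param seed integer seed; required when any noise source is active.
#' @return an [expr_set()] with genes x (conditions x days x replicates)
#'   values and sample annotations (`sampleID`, `condition`, `day`,
#'   `replicate`).
#' @export
generate_dataset <- function(truth, design = simulated_design(),
                             obs_noise_sd = 0.05, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(design, "simulated_design"),
            is_number(obs_noise_sd), obs_noise_sd >= 0)
  if ((truth$noise_sd > 0 || obs_noise_sd > 0) && is.null(seed)) {
    stop("seed must be set when noise_sd or obs_noise_sd is positive ",
         "(reproducibility contract)")
  }
  n <- length(truth$genes)
  n_steps <- max(design$days)
  x <- mrna_drive(truth, 0:(n_steps - 1L))
  with_seed(seed, {
    cols <- list()
    ann <- list()
    for (ic in seq_along(design$conditions)) {
      cond <- design$conditions[ic]
      schedule <- condition_schedule(truth, design, ic, n_steps)
      eps <- if (truth$noise_sd > 0) {
        matrix(stats::rnorm(n * n_steps, 0, truth$noise_sd), n, n_steps)
      } else NULL
      Z <- sim_path(truth, schedule, truth$baseline, x = x, eps = eps)
      tag <- gsub("[^A-Za-z0-9]+", ".", cond)
      for (day in design$days) {
        for (rep_i in seq_len(design$replicates)) {
          obs <- Z[, day + 1L]
          if (obs_noise_sd > 0) {
            obs <- obs + stats::rnorm(n, 0, obs_noise_sd)
          }
          id <- sprintf("%s_d%d_r%d", tag, day, rep_i)
          cols[[id]] <- obs
          ann[[id]] <- data.frame(sampleID = id, condition = cond,
                                  day = day, replicate = rep_i,
                                  stringsAsFactors = FALSE)
        }
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- truth$genes
    expr_set(values, do.call(rbind, c(ann, list(make.row.names = FALSE))))
  })
}

#' Candidate interaction network with decoys
#'
#' Returns the true undirected edges plus `round(decoy_ratio * n_true)`
#' decoy edges sampled uniformly without replacement from the non-true
#' pairs.  Decoys have zero activity in every stage.
#'
#' @param truth a [ground_truth()] object.
#' @param decoy_ratio nonnegative decoy-to-true ratio.
#' @param seed seed for the decoy draw.
#' @return data frame with columns `source`, `target`, `is_true`.
#' @export
generate_candidate_network <- function(truth, decoy_ratio = 1, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"),
            is_number(decoy_ratio), decoy_ratio >= 0)
  n <- length(truth$genes)
  true <- truth$edges[, c("source", "target")]
  n_decoy <- round(decoy_ratio * nrow(true))
  if (n_decoy == 0) {
    return(data.frame(true, is_true = TRUE, stringsAsFactors = FALSE))
  }
  idx_mat <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  all_keys <- pair_key(truth$genes[idx_mat[, 1L]], truth$genes[idx_mat[, 2L]])
  free <- which(!all_keys %in% pair_key(true$source, true$target))
  if (n_decoy > length(free)) {
    stop("requested ", n_decoy, " decoys but only ", length(free),
         " non-true pairs are available")
  }
  sel <- with_seed(seed, sort(sample(free, n_decoy)))
  decoys <- data.frame(source = truth$genes[idx_mat[sel, 1L]],
                       target = truth$genes[idx_mat[sel, 2L]],
                       stringsAsFactors = FALSE)
  out <- rbind(data.frame(true, is_true = TRUE, stringsAsFactors = FALSE),
               data.frame(decoys, is_true = FALSE, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
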