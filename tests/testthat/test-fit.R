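test_that("choose_L scales with the parameter count", {
  expect_equal(choose_L(5, 4), 28L)
  expect_equal(choose_L(0, 3), 6L)
  expect_equal(choose_L(10, 5), 60L)
  expect_error(choose_L(3, 2.5), "multiplier")
})

test_that("spline interpolation reproduces knots, lines and constants", {
  genes <- paste0("g", 1:3)
  days <- 0:6
  vals <- rbind(2 * days + 1, rep(3.5, 7), sin(days))
  p <- stage_profile("I", genes, days, vals)
  # matching grid: identity
  same <- interpolate_profile(p, 7L)
  expect_equal(same$values, p$values, tolerance = 1e-12)
  # refined grid: linear data stay exactly linear, constants constant
  fine <- interpolate_profile(p, 25L)
  grid <- fine$days
  expect_equal(unname(fine$values[1, ]), 2 * grid + 1, tolerance = 1e-10)
  expect_equal(unname(fine$values[2, ]), rep(3.5, 25), tolerance = 1e-12)
  # original knots are reproduced where the grids coincide (ends)
  expect_equal(fine$values[3, c(1, 25)], p$values[3, c(1, 7)],
               tolerance = 1e-12)
  expect_error(interpolate_profile(p, 5L), "must be >=")
  p3 <- stage_profile("I", genes, 0:2, vals[, 1:3])
  expect_error(interpolate_profile(p3, 10L), ">= 4 time points")
})

test_that("AIC penalises parameters and rewards fit", {
  expect_equal(aic_score(28, 28, 3), 6)
  expect_equal(aic_score(28, 28, 4) - aic_score(28, 28, 3), 2)
  expect_equal(aic_score(14, 28, 3, "aic") - aic_score(28, 28, 3, "aic"),
               -28 * log(2), tolerance = 1e-12)
  # exact fits are floored, not -Inf
  expect_true(is.finite(aic_score(0, 20, 2)))
  # AICc adds the small-sample correction
  expect_equal(aic_score(10, 20, 3, "aicc") - aic_score(10, 20, 3, "aic"),
               2 * 3 * 4 / (20 - 3 - 1))
})

test_that("least squares recovers planted coefficients exactly", {
  tr <- small_truth(n_genes = 8L, n_edges = 10L, noise_sd = 0, seed = 3L)
  cand <- tr$candidate_edges
  qmax <- max(table(c(cand$source, cand$target)))
  L <- choose_L(qmax, 4)
  prof <- simulate_stage_profile(tr, "I", n_steps = L - 1, noise_sd = 0)
  nbrs <- function(g) sort(unique(c(cand$target[cand$source == g],
                                    cand$source[cand$target == g])))
  g <- tr$genes[which.max(vapply(tr$genes, function(g) length(nbrs(g)),
                                 integer(1)))]
  prob <- regression_problem(prof, g, nbrs(g))
  fit <- fit_target(prob)
  expect_lt(fit$rss, 1e-18)
  truthB <- as.matrix(tr$stage_networks[["I"]])
  expect_equal(fit$b[sort(names(fit$b))],
               truthB[g, sort(names(fit$b))], tolerance = 1e-8)
  expect_equal(fit$alpha, unname(tr$alpha[g]), tolerance = 1e-8)
  expect_equal(fit$beta, unname(tr$beta[g]), tolerance = 1e-8)
})

test_that("duplicated neighbour series make the design rank deficient", {
  z <- matrix(runif(4 * 20, 1, 2), 4, 20,
              dimnames = list(paste0("g", 1:4), NULL))
  z[3, ] <- z[2, ] # duplicate series -> identical interaction columns
  expect_error(fit_target(regression_problem(z, "g1", c("g2", "g3"))),
               "rank-deficient")
})

test_that("without a distinct mRNA series the translation term is merged", {
  tr <- small_truth(n_genes = 6L, n_edges = 6L, noise_sd = 0, seed = 9L)
  prof <- simulate_stage_profile(tr, "I", n_steps = 31L, noise_sd = 0)
  prof$mrna <- NULL
  prob <- regression_problem(prof, tr$genes[1], character(0))
  expect_false(prob$has_mrna)
  fit <- fit_target(prob)
  expect_identical(fit$alpha, 0)
})

test_that("AIC pruning discards decoys and keeps true interactions", {
  tr <- small_truth(n_genes = 6L, n_edges = 4L, noise_sd = 0, seed = 5L)
  cand <- generate_candidate_network(tr, decoy_ratio = 1, seed = 2L)
  qmax <- max(table(c(cand$source, cand$target)))
  L <- choose_L(qmax, 4)
  prof <- simulate_stage_profile(tr, "I", n_steps = L - 1, noise_sd = 0)
  truthB <- as.matrix(tr$stage_networks[["I"]])
  for (g in tr$genes) {
    nb <- sort(unique(c(cand$target[cand$source == g],
                        cand$source[cand$target == g])))
    if (!length(nb)) next
    fit <- prune_by_aic(regression_problem(prof, g, nb))
    expect_setequal(fit$retained, names(which(truthB[g, nb] != 0)))
  }
})

test_that("pruning a target without neighbours returns the base model", {
  tr <- small_truth(n_genes = 5L, n_edges = 3L, noise_sd = 0, seed = 2L)
  prof <- simulate_stage_profile(tr, "I", n_steps = 20L, noise_sd = 0)
  fit <- prune_by_aic(regression_problem(prof, tr$genes[1], character(0)))
  expect_length(fit$retained, 0)
  expect_equal(fit$strategy, "full")
})

test_that("greedy backward elimination tracks the exhaustive optimum", {
  exact <- 0L
  close2 <- 0L
  n_trials <- 20L
  for (s in seq_len(n_trials)) {
    tr <- ground_truth(n_genes = 8L, n_true_edges = 9L, noise_sd = 0.05,
                       seed = 100L + s)
    cand <- generate_candidate_network(tr, decoy_ratio = 1, seed = s)
    deg <- table(c(cand$source, cand$target))
    g <- names(deg)[deg <= 6][1]
    if (is.na(g)) next
    L <- choose_L(max(deg), 4)
    prof <- simulate_stage_profile(tr, "II", n_steps = L - 1, seed = s)
    nb <- sort(unique(c(cand$target[cand$source == g],
                        cand$source[cand$target == g])))
    prob <- regression_problem(prof, g, nb)
    ex <- prune_by_aic(prob, strategy = "exhaustive")
    gr <- prune_by_aic(prob, strategy = "greedy")
    expect_gte(gr$aic, ex$aic - 1e-9) # exhaustive is the optimum
    if (abs(gr$aic - ex$aic) < 1e-6) exact <- exact + 1L
    if (gr$aic <= ex$aic + 2) close2 <- close2 + 1L
  }
  # steepest-descent backward elimination finds the optimum on most
  # instances and is rarely more than 2 AIC units away
  expect_gte(exact, ceiling(0.6 * n_trials))
  expect_gte(close2, ceiling(0.9 * n_trials))
})

test_that("stage network construction respects the candidate support", {
  tr <- small_truth(n_genes = 10L, n_edges = 12L, noise_sd = 0.05, seed = 4L)
  cand <- generate_candidate_network(tr, decoy_ratio = 1, seed = 4L)
  prof <- simulate_stage_profile(tr, "II", n_steps = 40L, seed = 4L)
  net <- suppressMessages(construct_stage_network(prof, cand))
  ed <- network_edges(net)
  cand_keys <- c(paste(cand$source, cand$target),
                 paste(cand$target, cand$source))
  expect_true(all(paste(ed$source, ed$target) %in% cand_keys))
  # disjoint candidates produce an empty network with a warning
  cand2 <- data.frame(source = "zz1", target = "zz2")
  expect_warning(net2 <- construct_stage_network(prof, cand2),
                 "no candidate edges")
  expect_equal(nrow(network_edges(net2)), 0)
})

test_that("full-pipeline fit recovers a small planted network exactly", {
  tr <- small_truth(n_genes = 10L, n_edges = 12L, noise_sd = 0, seed = 8L)
  cand <- generate_candidate_network(tr, decoy_ratio = 1, seed = 8L)
  qmax <- max(table(c(cand$source, cand$target)))
  L <- choose_L(qmax, 4)
  prof <- simulate_stage_profile(tr, "III", n_steps = L - 1, noise_sd = 0)
  net <- suppressMessages(construct_stage_network(prof, cand))
  expect_equal(as.matrix(net$b), as.matrix(tr$stage_networks[["III"]]),
               tolerance = 1e-6)
  stats <- edge_recovery_stats(net, tr, "III")
  expect_equal(stats$precision, 1)
  expect_equal(stats$recall, 1)
})
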