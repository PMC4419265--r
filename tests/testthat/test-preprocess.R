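test_that("quantile normalization equalises column distributions", {
  m <- cbind(s1 = c(1, 3, 5), s2 = c(2, 4, 6))
  rownames(m) <- paste0("g", 1:3)
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(1.5, 3.5, 5.5))
  expect_equal(unname(qn[, 2]), c(1.5, 3.5, 5.5))
  # identical samples are a fixed point
  m2 <- cbind(a = c(2, 7, 1), b = c(2, 7, 1))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(quantile_normalize(m2), m2, ignore_attr = TRUE)
  # ties receive the mean of the reference values at the tied ranks
  m3 <- cbind(a = c(1, 1, 2), b = c(3, 4, 5))
  rownames(m3) <- paste0("g", 1:3)
  qn3 <- quantile_normalize(m3)
  expect_equal(unname(qn3[, 1]), c(2.25, 2.25, 3.5))
})

test_that("quantile normalization is idempotent with identical order stats", {
  set.seed(1)
  m <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  qn <- quantile_normalize(m)
  sorted <- apply(qn, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-12)
  expect_error(quantile_normalize(cbind(c(1, NA), c(2, 3))), "non-finite")
})

test_that("stage profiles pull the right condition/day segments", {
  days <- c(0, 1, 3, 5, 7, 11, 13)
  genes <- paste0("G", 1:4)
  cols <- list(); ann <- list()
  conds <- c("LSB", "LSB/S/F8", "LSB/S/F8/CHIR")
  for (ci in seq_along(conds)) {
    for (d in days) {
      for (r in 1:2) {
        id <- sprintf("c%d_d%d_r%d", ci, d, r)
        # encode condition and day in the value; replicates offset by r
        cols[[id]] <- rep(100 * ci + d, 4) + (r - 1.5) * 2
        ann[[id]] <- data.frame(sampleID = id, condition = conds[ci],
                                day = d, replicate = r)
      }
    }
  }
  values <- do.call(cbind, cols); rownames(values) <- genes
  es <- expr_set(values, do.call(rbind, ann))
  designs <- stage_designs()
  pI <- assemble_stage_profile(es, designs$I)
  # stage I: only the first condition, replicate-averaged (offsets cancel)
  expect_equal(unname(pI$values[1, ]), 100 + days)
  pII <- assemble_stage_profile(es, designs$II)
  expect_equal(unname(pII$values[1, ]),
               c(100 + c(0, 1), 200 + c(3, 5, 7, 11, 13)))
  pIII <- assemble_stage_profile(es, designs$III)
  expect_equal(unname(pIII$values[1, ]),
               c(100 + c(0, 1), 200 + 3, 300 + c(5, 7, 11, 13)))
  # replicate mean: values 1,2,3 average to 2
  es2 <- toy_eset(n_genes = 2, days = c(0, 1, 3, 5), reps = 3,
                  value_fun = function(d) c(0, 0))
  es2$values[1, es2$annotations$day == 0] <- c(1, 2, 3)
  p <- assemble_stage_profile(es2, stage_design("x", rep("LSB", 4),
                                                c(0, 1, 3, 5)))
  expect_equal(unname(p$values[1, 1]), 2)
  # missing design cells are named in the error
  expect_error(
    assemble_stage_profile(es2, stage_design("x", "LSB", 99)),
    "day 99")
})

test_that("stage profile assembly commutes with gene subsetting", {
  tr <- small_truth(noise_sd = 0.05)
  es <- generate_dataset(tr, seed = 2L)
  d <- stage_designs()$II
  keep <- tr$genes[c(2, 5, 7)]
  p_all <- assemble_stage_profile(es, d)
  p_sub <- assemble_stage_profile(es, d, genes = keep)
  expect_equal(p_sub$values, p_all$values[keep, ])
})

test_that("ANOVA F and p agree with a per-gene linear model", {
  es <- toy_eset(n_genes = 6, reps = 3, noise = 1,
                 value_fun = function(d) c(d, 0, d / 2, 0, sqrt(d), 0))
  de <- anova_de_filter(es, stage_designs()$I, fdr_threshold = 0.05)
  for (i in seq_len(6)) {
    y <- es$values[i, ]
    fac <- factor(es$annotations$day)
    a <- stats::anova(stats::lm(y ~ fac))
    expect_equal(de$F[i], a$`F value`[1], tolerance = 1e-10)
    expect_equal(de$p[i], a$`Pr(>F)`[1], tolerance = 1e-10)
  }
  expect_equal(de$p_adj, stats::p.adjust(de$p, "BH"))
})

test_that("constant genes get p = 1 and thresholds behave at the extremes", {
  es <- toy_eset(n_genes = 4, reps = 3, noise = 0.2,
                 value_fun = function(d) c(d, 2 * d, 0, 0))
  es$values[4, ] <- 7 # exactly constant
  expect_warning(de <- anova_de_filter(es, stage_designs()$I, 0.05),
                 "constant")
  expect_equal(de$p[4], 1)
  expect_false(de$selected[4])
  # threshold near 1 keeps every gene whose adjusted p is below 1
  # (a null gene can be adjusted to exactly 1 by BH), none near 0
  suppressWarnings({
    de_all <- anova_de_filter(es, stage_designs()$I, 1 - 1e-12)
    de_none <- anova_de_filter(es, stage_designs()$I, 1e-300)
  })
  expect_true(all(de_all$selected[de_all$p_adj < 1]))
  expect_true(all(de_all$selected[1:2]))
  expect_false(any(de_none$selected))
})

test_that("the DE filter demands replicated time points", {
  es <- toy_eset(n_genes = 3, reps = 1, noise = 0.1,
                 value_fun = function(d) rep(d, 3))
  expect_error(anova_de_filter(es, stage_designs()$I, 0.05),
               ">= 2 replicates")
})

test_that("day-0 baseline subtraction centres each condition at day 0", {
  tr <- small_truth(noise_sd = 0)
  es <- generate_dataset(tr, obs_noise_sd = 0, seed = 1L)
  es0 <- subtract_baseline(es)
  ann <- es0$annotations
  for (cond in unique(ann$condition)) {
    base <- rowMeans(es0$values[, ann$condition == cond & ann$day == 0,
                                drop = FALSE])
    expect_equal(unname(base), rep(0, nrow(es0$values)), tolerance = 1e-12)
  }
})

test_that("probe collapse keeps the most variable probe per gene", {
  m <- rbind(p1 = c(1, 2, 3), p2 = c(10, 20, 30), p3 = c(5, 5, 5))
  colnames(m) <- paste0("s", 1:3)
  map <- c(p1 = "GA", p2 = "GA", p3 = "GB")
  out <- collapse_probes(m, map)
  expect_equal(sort(rownames(out)), c("GA", "GB"))
  expect_equal(unname(out["GA", ]), c(10, 20, 30))
})
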