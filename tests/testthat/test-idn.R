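test_that("IDN algebra: self-difference is empty, swap negates", {
  set.seed(42)
  B1 <- random_activity(8)
  B2 <- random_activity(8)
  idn_same <- idn_from_matrices(B1, B1)
  expect_equal(Matrix::nnzero(idn_same$D), 0)
  expect_equal(nrow(idn_same$edges), 0)
  ab <- idn_from_matrices(B1, B2)
  ba <- idn_from_matrices(B2, B1)
  expect_equal(as.matrix(ab$D), -as.matrix(ba$D), tolerance = 1e-15)
  # difference matches the dense subtraction entrywise
  expect_equal(as.matrix(ab$D), B2 - B1, tolerance = 1e-15,
               ignore_attr = TRUE)
})

test_that("an edge present in one stage only carries its full activity", {
  B1 <- matrix(0, 3, 3)
  B2 <- matrix(0, 3, 3)
  B2[1, 2] <- 0.3
  idn <- idn_from_matrices(B1, B2)
  expect_equal(nrow(idn$edges), 1)
  expect_equal(idn$edges$d, 0.3)
  expect_equal(idn$edges$existence, "emerged")
  expect_equal(idn$edges$direction, "enhancing")
})

test_that("edge-change classes cover every sign transition", {
  # enhancing: + -> ++, -- -> -, 0 -> +, - -> 0
  expect_equal(classify_edge_change(0.5, 1.2),
               data.frame(direction = "enhancing", existence = "coexisting"))
  expect_equal(classify_edge_change(-0.5, -0.2),
               data.frame(direction = "enhancing", existence = "coexisting"))
  expect_equal(classify_edge_change(NA, 0.7),
               data.frame(direction = "enhancing", existence = "emerged"))
  expect_equal(classify_edge_change(-0.3, NA),
               data.frame(direction = "enhancing", existence = "diminished"))
  # attenuating: ++ -> +, - -> --, + -> 0, 0 -> -
  expect_equal(classify_edge_change(1.2, 0.5),
               data.frame(direction = "attenuating", existence = "coexisting"))
  expect_equal(classify_edge_change(-0.2, -0.5),
               data.frame(direction = "attenuating", existence = "coexisting"))
  expect_equal(classify_edge_change(0.5, NA),
               data.frame(direction = "attenuating", existence = "diminished"))
  expect_equal(classify_edge_change(NA, -0.7),
               data.frame(direction = "attenuating", existence = "emerged"))
  # equal activities: no direction
  expect_equal(classify_edge_change(0.4, 0.4)$direction, "none")
  expect_error(classify_edge_change(NA, NA), "absent in both")
})

test_that("relevance scores follow the degree-normalised row sums", {
  D <- matrix(0, 4, 4)
  D[1, ] <- c(0, 1.0, -2.0, 0.5) # degree 3, RS = 3.5 / 3
  D[2, 4] <- -7 # degree 1, RS = 7
  idn <- idn_from_matrices(matrix(0, 4, 4), D)
  rs <- relevance_scores(idn)
  expect_equal(rs$RS[1], 3.5 / 3)
  expect_equal(rs$degree[1], 3L)
  expect_equal(rs$RS[2], 7)
  expect_equal(rs$RS[3], 0) # all-zero row
  expect_equal(rs$degree[3], 0L)
  expect_equal(relevance_score_protein(idn, rs$gene[2]), 7)
  expect_error(relevance_score_protein(idn, "nope"), "not in the IDN")
})

test_that("ranking matches a brute-force oracle on a random sparse IDN", {
  set.seed(7)
  n <- 50
  B1 <- random_activity(n, density = 0.05)
  B2 <- random_activity(n, density = 0.05)
  idn <- idn_from_matrices(B1, B2)
  oracle <- brute_rs(B2 - B1)
  names(oracle) <- sprintf("g%02d", seq_len(n))
  ord <- order(-oracle, names(oracle))
  tab <- rank_proteins(idn)
  expect_equal(tab$protein, names(oracle)[ord])
  expect_equal(tab$RS, unname(oracle[ord]), tolerance = 1e-12)
  # ties break lexicographically
  Dt <- matrix(0, 3, 3)
  Dt[2, 1] <- 1; Dt[3, 1] <- 1
  tt <- rank_proteins(idn_from_matrices(matrix(0, 3, 3), Dt), top_n = 2)
  expect_equal(tt$protein, c("g02", "g03"))
})

test_that("RS invariants: sign flips, positive scaling, stage swap", {
  set.seed(11)
  for (i in 1:25) {
    D <- random_activity(6, density = 0.4)
    base <- brute_rs(D)
    idn <- idn_from_matrices(matrix(0, 6, 6), D)
    rs <- relevance_scores(idn)$RS
    expect_equal(rs, base, tolerance = 1e-12)
    # sign flip leaves RS unchanged
    rs_neg <- relevance_scores(idn_from_matrices(matrix(0, 6, 6), -D))$RS
    expect_equal(rs_neg, rs, tolerance = 1e-12)
    # positive scaling scales RS linearly
    cfac <- runif(1, 0.5, 3)
    rs_scaled <- relevance_scores(
      idn_from_matrices(matrix(0, 6, 6), cfac * D))$RS
    expect_equal(rs_scaled, cfac * rs, tolerance = 1e-12)
    # swapping the stages leaves RS unchanged (|d| symmetric)
    rs_swap <- relevance_scores(idn_from_matrices(D, matrix(0, 6, 6)))$RS
    expect_equal(rs_swap, rs, tolerance = 1e-12)
  }
})

test_that("neighbourhood extraction honours radius and components", {
  D <- matrix(0, 6, 6)
  # star centred at g01: edges to g02..g04; chain g04-g05; g06 isolated
  D[1, 2] <- D[1, 3] <- D[1, 4] <- 1
  D[4, 5] <- 1
  idn <- idn_from_matrices(matrix(0, 6, 6), D)
  star <- extract_neighborhood(idn, "g01", radius = 1)
  expect_setequal(star$genes, c("g01", "g02", "g03", "g04"))
  all_comp <- extract_neighborhood(idn, "g01", radius = 10)
  expect_setequal(all_comp$genes, c("g01", "g02", "g03", "g04", "g05"))
  singleton <- extract_neighborhood(idn, "g06", radius = 1)
  expect_equal(singleton$genes, "g06")
  expect_warning(sub <- extract_neighborhood(idn, c("g01", "zz"), 1),
                 "skipped")
  expect_setequal(sub$genes, c("g01", "g02", "g03", "g04"))
})

test_that("node status tracks presence of incident edges across stages", {
  B1 <- matrix(0, 4, 4); B2 <- matrix(0, 4, 4)
  B1[1, 2] <- 0.2              # g01-g02 present early only
  B2[3, 4] <- 0.5              # g03-g04 present late only
  B1[1, 3] <- 0.1; B2[1, 3] <- 0.4 # g01, g03 in both
  idn <- idn_from_matrices(B1, B2)
  st <- setNames(idn$nodes$status, idn$nodes$gene)
  expect_equal(unname(st["g01"]), "coexisting")
  expect_equal(unname(st["g02"]), "diminished")
  expect_equal(unname(st["g04"]), "emerged")
})
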