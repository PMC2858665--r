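test_that("cell labeling handles degenerate and planted-signal configurations", {
  set.seed(31)
  g1 <- rbinom(1000, 2, 0.5)
  g2 <- rbinom(1000, 2, 0.5)

  # constant residuals: zero t everywhere, all cells O
  part0 <- mbmdr_label_cells(rep(1.5, 1000), g1, g2)
  expect_true(all(part0$labels == "O"))
  st0 <- mbmdr_pair_statistics(rep(1.5, 1000), g1, g2, part0)
  expect_equal(c(st0$t_h, st0$t_l), c(0, 0))

  # a single strongly elevated cell is the unique H
  y <- rnorm(1000, 0, 1e-3)
  y[g1 == 2 & g2 == 2] <- 5
  part <- mbmdr_label_cells(y, g1, g2)
  expect_equal(part$labels["2", "2"], "H")
  expect_equal(sum(part$labels == "H"), 1L)

  # empty cells are O
  g1b <- pmin(g1, 1)  # no homozygote-minor at locus 1
  partb <- mbmdr_label_cells(rnorm(1000), g1b, g2)
  expect_true(all(partb$labels["2", ] == "O"))
  expect_true(all(partb$cell_counts["2", ] == 0))
})

test_that("labels and statistics match an independent t-test implementation", {
  set.seed(32)
  for (r in 1:20) {
    n <- sample(150:400, 1)
    g1 <- rbinom(n, 2, runif(1, 0.15, 0.5))
    g2 <- rbinom(n, 2, runif(1, 0.15, 0.5))
    y <- rnorm(n) + 0.4 * (g1 == 1) * (g2 == 1) * rbinom(1, 1, 0.5)
    if (r %% 3 == 0) {  # sprinkle missing data: available-case handling
      y[sample(n, 5)] <- NA
      g1[sample(n, 5)] <- NA
    }
    ref <- brute_mbmdr(y, g1, g2)
    part <- mbmdr_label_cells(y, g1, g2)
    st <- mbmdr_pair_statistics(y, g1, g2, part)
    expect_equal(unname(part$labels), ref$labels)
    expect_equal(st$n_used, ref$n_used)
    expect_lt(abs(st$t_h - ref$t_h), 1e-10)
    expect_lt(abs(st$t_l - ref$t_l), 1e-10)
  }
})

test_that("cell tests are calibrated: non-O frequency matches cell_alpha", {
  set.seed(33)
  non_o <- 0L; testable_total <- 0L
  for (r in 1:300) {
    g1 <- rbinom(500, 2, 0.3)
    g2 <- rbinom(500, 2, 0.3)
    part <- mbmdr_label_cells(rnorm(500), g1, g2)
    testable <- part$cell_counts >= 2 &
      (sum(part$cell_counts) - part$cell_counts) >= 2
    non_o <- non_o + sum(part$labels[testable] != "O")
    testable_total <- testable_total + sum(testable)
  }
  expect_gt(testable_total, 2000)
  expect_lt(abs(non_o / testable_total - 0.1), 0.02)
})

test_that("screen enumerates pairs and respects symmetries", {
  set.seed(34)
  n <- 300
  G <- sapply(1:10, function(s) rbinom(n, 2, 0.3))
  colnames(G) <- paste0("SNP", 1:10)
  y <- rnorm(n) + 0.6 * (G[, 1] >= 1) * (G[, 2] >= 1)
  sc <- mbmdr_screen(y, G)
  expect_equal(nrow(sc$pairs), choose(10, 2))
  expect_equal(sc$best_pair, c("SNP1", "SNP2"))

  # permuting individuals leaves every statistic unchanged
  ord <- sample(n)
  sc2 <- mbmdr_screen(y[ord], G[ord, ])
  expect_equal(sc2$pairs$max_stat, sc$pairs$max_stat, tolerance = 1e-12)

  # affine invariance: a*y + b identical; negation swaps H and L
  sc3 <- mbmdr_screen(3 * y + 10, G)
  expect_equal(sc3$pairs$t_h, sc$pairs$t_h, tolerance = 1e-9)
  expect_equal(sc3$pairs$labels, sc$pairs$labels)
  sc4 <- mbmdr_screen(-y, G)
  expect_equal(sc4$pairs$t_h, sc$pairs$t_l, tolerance = 1e-9)
  expect_equal(sc4$pairs$labels, chartr("HL", "LH", sc$pairs$labels))

  # a duplicated SNP gives order-independent results
  G2 <- cbind(G[, 1:3], copy = G[, 3])
  p34 <- mbmdr_screen(y, G2)$pairs
  row <- p34[p34$snp_a == "SNP3" & p34$snp_b == "copy", ]
  self <- mbmdr_pair_statistics(y, G[, 3], G[, 3])
  expect_equal(row$t_h, self$t_h, tolerance = 1e-10)
})

test_that("H versus L with no populated O cells gives equal statistics", {
  set.seed(35)
  # only two populated cells, strongly separated: H and L partition the data
  g1 <- rep(c(0, 2), each = 50)
  g2 <- rep(c(0, 2), each = 50)
  y <- c(rnorm(50, 3), rnorm(50, -3))
  part <- mbmdr_label_cells(y, g1, g2)
  expect_equal(part$labels["0", "0"], "H")
  expect_equal(part$labels["2", "2"], "L")
  st <- mbmdr_pair_statistics(y, g1, g2, part)
  expect_equal(st$t_h, st$t_l, tolerance = 1e-12)
})
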