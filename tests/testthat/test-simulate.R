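test_that("HWE frequencies and model mean grids are exact", {
  expect_equal(unname(hwe_genotype_freqs(0.5)), c(0.25, 0.5, 0.25))
  expect_equal(unname(hwe_genotype_freqs(0.1)), c(0.81, 0.18, 0.01))
  for (p in c(0.07, 0.3, 0.9))
    expect_equal(sum(hwe_genotype_freqs(p)), 1)
  expect_error(hwe_genotype_freqs(0), "\\(0, 1\\)")

  # scaling: variance of the means under HWE frequencies equals g2
  for (m in c("M27", "M170")) for (p in c(0.1, 0.25, 0.5)) {
    mu <- build_model_means(m, p, g2 = 0.05)
    expect_equal(variance_decomposition(mu, p)$sigma2_M, 0.05,
                 tolerance = 1e-12)
  }
  # closed-form scale for M27 at p = 0.5: P(both loci carry a minor
  # allele) = 0.75^2 = 0.5625, Bernoulli variance 0.5625 * 0.4375
  mu <- build_model_means("M27", 0.5, g2 = 0.1)
  expect_equal(max(mu), sqrt(0.1 / (0.5625 * 0.4375)), tolerance = 1e-12)
  expect_equal(min(mu), 0)

  expect_true(all(build_model_means("M27", 0.25, g2 = 0) == 0))
})

test_that("variance decomposition reproduces the analytic main/epistasis table", {
  tab <- rbind(
    c(model = "M27", p = 0.10, main = 0.16, epi = 0.68),
    c("M27", 0.25, 0.30, 0.39),
    c("M27", 0.50, 0.43, 0.14),
    c("M170", 0.10, 0.29, 0.42),
    c("M170", 0.25, 0.06, 0.88),
    c("M170", 0.50, 0.00, 1.00))
  for (i in seq_len(nrow(tab))) {
    p <- as.numeric(tab[i, "p"])
    d <- variance_decomposition(build_model_means(tab[i, "model"], p, 0.1), p)
    expect_equal(round(d$sigma2_A / d$sigma2_M, 2),
                 as.numeric(tab[i, "main"]))
    expect_equal(round(d$sigma2_B / d$sigma2_M, 2),
                 as.numeric(tab[i, "main"]))
    expect_equal(round(d$sigma2_I / d$sigma2_M, 2),
                 as.numeric(tab[i, "epi"]))
  }

  # brute-force enumeration oracle on random mean grids
  set.seed(41)
  for (r in 1:10) {
    mu <- matrix(rnorm(9), 3, 3)
    p <- runif(1, 0.05, 0.95)
    fr <- hwe_genotype_freqs(p)
    d <- variance_decomposition(mu, p)
    m_tot <- 0; mbar <- 0
    for (j in 1:3) for (k in 1:3) mbar <- mbar + fr[j] * fr[k] * mu[j, k]
    for (j in 1:3) for (k in 1:3)
      m_tot <- m_tot + fr[j] * fr[k] * (mu[j, k] - mbar)^2
    expect_equal(d$sigma2_M, unname(m_tot), tolerance = 1e-12)
    expect_equal(d$sigma2_A + d$sigma2_B + d$sigma2_I, d$sigma2_M)
    # additive grids have exactly zero epistatic variance
    add <- outer(rnorm(3), rnorm(3), `+`)
    expect_lt(abs(variance_decomposition(add, p)$sigma2_I), 1e-12)
  }
})

test_that("additive null surface removes epistasis but keeps marginals", {
  mu <- build_model_means("M27", 0.5, g2 = 0.1)
  add <- additive_null_means(mu, 0.5)
  d0 <- variance_decomposition(mu, 0.5)
  d1 <- variance_decomposition(add, 0.5)
  expect_lt(abs(d1$sigma2_I), 1e-12)
  expect_equal(d1$sigma2_M, d0$sigma2_A + d0$sigma2_B, tolerance = 1e-12)
  # ratio of remaining to original two-locus variance: twice the main share
  expect_equal(round(d1$sigma2_M / d0$sigma2_M, 2), 2 * 0.43)
  fr <- hwe_genotype_freqs(0.5)
  expect_equal(drop(add %*% fr), drop(mu %*% fr), tolerance = 1e-12)
  expect_equal(drop(fr %*% add), drop(fr %*% mu), tolerance = 1e-12)

  spec <- no_epistasis_model("M27", 0.5, 0.1, 0.3)
  expect_equal(spec$sigma2_g, 0.3 - d1$sigma2_M, tolerance = 1e-12)
  expect_equal(spec$sigma2_e, 0.7)
  expect_error(no_epistasis_model("M170", 0.5, 0.1, 0.3), "pure epistasis")
})

test_that("pedigree generator matches the family-size design", {
  ped <- simulate_pedigrees(10000, seed = 51)
  sizes <- table(ped$fid)
  expect_true(all(sizes %in% 3:5))
  mean_children <- mean(sizes) - 2
  expect_lt(abs(mean_children - 2), 0.02)
  expect_silent(validate_pedigree(ped))
})

test_that("genotype generator respects HWE, Mendel, and linkage equilibrium", {
  # founders-only pedigree: large-sample HWE goodness of fit
  n <- 100000L
  founders <- pedigree(fid = as.character(seq_len(n)),
                       iid = paste0("f", seq_len(n)),
                       pat = "0", mat = "0")
  g <- simulate_genotypes(founders, c(SNP1 = 0.3), seed = 52)
  expected <- hwe_genotype_freqs(0.3) * n
  chi <- sum((table(factor(g, levels = 0:2)) - expected)^2 / expected)
  expect_lt(chi, qchisq(0.999, df = 2))

  # Mendelian: two reference-homozygote parents only have 0-count children
  ped <- simulate_pedigrees(200, seed = 53)
  G <- simulate_genotypes(ped, c(SNP1 = 0.4), seed = 53)
  parents_zero <- ped$fid[!duplicated(ped$fid)][
    vapply(unique(ped$fid), function(f)
      all(G[paste0(f, "_", 1:2), 1] == 0), TRUE)]
  kids <- ped$iid[ped$fid %in% parents_zero & ped$pat != "0"]
  expect_true(all(G[kids, 1] == 0))

  # linkage equilibrium: parental genotype correlation compatible with 0
  ds <- simulate_dataset(two_locus_model("M27", 0.25, 0, 0.3),
                         n_families = 250, seed = 54)
  par_ids <- ds$ped$iid[ds$ped$pat == "0"]
  ct <- cor.test(ds$geno[par_ids, "SNP1"], ds$geno[par_ids, "SNP2"])
  expect_true(ct$conf.int[1] < 0 && ct$conf.int[2] > 0)
})

test_that("phenotype generator matches the prescribed moments", {
  # pure polygenic + environment: unit variance, sib covariance = sigma2_G/2
  spec <- two_locus_model("M27", p = 0.25, g2 = 0, h2 = 0.3)
  ped <- simulate_pedigrees(10000, seed = 61)
  G <- matrix(0L, nrow(ped), 2, dimnames = list(ped$iid, c("SNP1", "SNP2")))
  set.seed(61)
  y <- simulate_phenotypes(spec, G, ped)
  expect_lt(abs(var(y) - 1), 3 * sqrt(2 / length(y)))
  expect_lt(abs(mean(y)), 0.02)
  sib1 <- paste0(unique(ped$fid), "_3")
  sib2 <- paste0(unique(ped$fid), "_4")
  has2 <- sib2 %in% ped$iid
  sib_cov <- cov(y[sib1[has2]], y[sib2[has2]])
  expect_lt(abs(sib_cov - 0.15), 0.03)

  # cell-mean recovery: regression on the 9 cell indicators estimates mu_jk
  spec2 <- two_locus_model("M27", p = 0.25, g2 = 0.1, h2 = 0.5)
  ds <- simulate_dataset(spec2, n_families = 2500, seed = 62)
  cell <- factor(paste0(ds$geno[names(ds$trait), "SNP1"],
                        ds$geno[names(ds$trait), "SNP2"]))
  fitlm <- lm(ds$trait ~ 0 + cell)
  est <- coef(fitlm)
  truth <- spec2$means[cbind(
    as.integer(substr(levels(cell), 1, 1)) + 1L,
    as.integer(substr(levels(cell), 2, 2)) + 1L)]
  n_cell <- table(cell)
  big <- n_cell >= 30
  expect_lt(max(abs(est[big] - truth[big])), 0.15)
  mu_bar <- sum(outer(hwe_genotype_freqs(0.25), hwe_genotype_freqs(0.25)) *
                spec2$means)
  expect_lt(abs(mean(ds$trait) - mu_bar), 0.05)
})

test_that("experiment grids have the designed dimensions", {
  expect_equal(nrow(experiment_grid("alternative")), 90L)
  expect_equal(nrow(experiment_grid("general_null")), 9L)
  expect_equal(nrow(experiment_grid("no_epistasis")), 75L)
})
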