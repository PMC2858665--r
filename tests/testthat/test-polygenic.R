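test_that("co-dominant coding follows the dummy-variable and complete-case rules", {
  g <- cbind(SNP1 = c(0, 1, 2, 1, 0), SNP2 = c(2, NA, 0, 1, 1))
  rownames(g) <- paste0("i", 1:5)
  X1 <- codominant_design(g, "SNP1")
  expect_equal(unname(X1["i1", ]), c(0, 0))
  expect_equal(unname(X1["i2", ]), c(1, 0))
  expect_equal(unname(X1["i3", ]), c(0, 1))
  # a missing genotype in any selected SNP voids the whole row
  X <- codominant_design(g)
  expect_true(all(is.na(X["i2", ])))
  expect_true(all(!is.na(X[c("i1", "i3", "i4", "i5"), ])))

  # monomorphic SNP and absent-category columns are dropped with a warning
  g2 <- cbind(SNPA = c(0, 0, 0, 0), SNPB = c(0, 2, 2, 0))
  expect_warning(X2 <- codominant_design(g2), "dropping")
  expect_equal(colnames(X2), "SNPB_hom")

  expect_error(codominant_design(cbind(A = c(0, 3))), "0/1/2")
})

test_that("identity relationship resolves to the sigma2_g = 0 boundary", {
  set.seed(21)
  n <- 40
  y <- stats::setNames(rnorm(n, mean = 3), paste0("s", 1:n))
  A <- diag(n); dimnames(A) <- list(names(y), names(y))
  fit <- fit_polygenic(y, A)
  expect_equal(fit$sigma2_g, 0)
  expect_true(fit$boundary)
  # total variance equals the ML variance of an intercept-only Gaussian fit
  expect_equal(fit$sigma2_e, mean((y - mean(y))^2), tolerance = 1e-8)
  # residuals equal the centered trait when no polygenic component is fit
  expect_equal(unname(fit$residuals), unname(y - mean(y)), tolerance = 1e-8)
  expect_lt(abs(mean(fit$residuals)), 1e-6 * sd(y))
})

test_that("variance components are recovered on simulated nuclear families", {
  sg <- se <- numeric(20)
  for (r in 1:20) {
    spec <- two_locus_model("M27", p = 0.25, g2 = 0, h2 = 0.3)
    ds <- simulate_dataset(spec, n_families = 250, seed = 100 + r)
    fit <- fit_polygenic(ds$trait, ds$A)
    sg[r] <- fit$sigma2_g
    se[r] <- fit$sigma2_e
  }
  expect_lt(abs(mean(sg) - 0.3), 0.05)
  expect_lt(abs(mean(se) - 0.7), 0.05)

  # sigma2_G = 0 truth: estimates pile up near the boundary
  sg0 <- numeric(10)
  for (r in 1:10) {
    spec <- two_locus_model("M27", p = 0.25, g2 = 0, h2 = 1e-9)
    ds <- simulate_dataset(spec, n_families = 250, seed = 300 + r)
    sg0[r] <- fit_polygenic(ds$trait, ds$A)$sigma2_g
  }
  expect_lt(mean(abs(sg0)), 0.05)
})

test_that("profile optimum dominates a direct-likelihood grid oracle", {
  spec <- two_locus_model("M27", p = 0.25, g2 = 0, h2 = 0.5)
  ds <- simulate_dataset(spec, n_families = 20, seed = 77)
  fit <- fit_polygenic(ds$trait, ds$A)
  X <- matrix(1, length(ds$trait), 1)
  grid <- seq(0, 1 - 1e-6, length.out = 100)
  ll_grid <- vapply(grid, function(g)
    direct_profile_ll(unname(ds$trait), X, ds$A, g), 0)
  expect_gte(fit$loglik, max(ll_grid) - 1e-6)
  # and the fitted point itself agrees with the direct evaluation
  gam <- fit$sigma2_g / (fit$sigma2_g + fit$sigma2_e)
  expect_equal(fit$loglik, direct_profile_ll(unname(ds$trait), X, ds$A, gam),
               tolerance = 1e-6)
})

test_that("residuals behave under scaling, shifts, and main-effect projection", {
  spec <- two_locus_model("M170", p = 0.25, g2 = 0.1, h2 = 0.5)
  ds <- simulate_dataset(spec, n_families = 80, seed = 55)
  fit <- fit_polygenic(ds$trait, ds$A)

  k <- 2.5
  fit_k <- fit_polygenic(k * ds$trait, ds$A)
  expect_equal(fit_k$sigma2_g, k^2 * fit$sigma2_g, tolerance = 1e-4)
  expect_equal(fit_k$sigma2_e, k^2 * fit$sigma2_e, tolerance = 1e-4)
  expect_equal(environmental_residuals(fit_k),
               k * environmental_residuals(fit), tolerance = 1e-4)

  fit_c <- fit_polygenic(ds$trait + 7, ds$A)
  expect_equal(environmental_residuals(fit_c),
               environmental_residuals(fit), tolerance = 1e-6)

  # with co-dominant adjustment the residuals carry no main effects
  X <- codominant_design(ds$geno, c("SNP1", "SNP2"))
  fit_adj <- fit_polygenic(ds$trait, ds$A, X)
  r <- environmental_residuals(fit_adj)
  coefs <- coef(lm(r ~ X))[-1]
  expect_lt(max(abs(coefs)), 1e-8)
})

test_that("residuals lose the positive familial correlation of the raw trait", {
  # Analytic reference: in a 2-parent 2-child family with trait covariance
  # sigma2_G A + sigma2_E I, the environmental residuals e = sigma2_E V^-1 y
  # have covariance sigma2_E^2 V^-1; BLUP shrinkage overshoots slightly, so
  # the sib-sib residual correlation is small and NEGATIVE, not zero.
  h2 <- 0.3
  A4 <- matrix(c(1, 0, .5, .5, 0, 1, .5, .5,
                 .5, .5, 1, .5, .5, .5, .5, 1), 4, 4)
  V <- h2 * A4 + (1 - h2) * diag(4)
  C <- (1 - h2)^2 * solve(V)
  ref_cor <- C[3, 4] / sqrt(C[3, 3] * C[4, 4])

  cors <- raw <- numeric(8)
  for (r in 1:8) {
    spec <- two_locus_model("M27", p = 0.25, g2 = 0, h2 = h2)
    ds <- simulate_dataset(spec, n_families = 250, seed = 400 + r)
    res <- environmental_residuals(fit_polygenic(ds$trait, ds$A))
    ped <- ds$ped
    sib1 <- paste0(unique(ped$fid), "_3")
    sib2 <- paste0(unique(ped$fid), "_4")
    has2 <- sib2 %in% ped$iid
    cors[r] <- cor(res[sib1[has2]], res[sib2[has2]])
    raw[r] <- cor(ds$trait[sib1[has2]], ds$trait[sib2[has2]])
  }
  # estimated variance components shrink less than the analytic ideal, so
  # the empirical mean lands between ref_cor and 0
  expect_gt(mean(cors), ref_cor - 0.05)
  expect_lt(mean(cors), 0.02)
  expect_lt(mean(abs(cors)), 0.1)
  # the raw trait's sibling correlation (~ 0.5 * sigma2_G) is gone
  expect_gt(mean(raw), 0.1)
})
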