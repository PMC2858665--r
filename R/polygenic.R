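#' Co-dominant dummy design for SNP main effects
#'
#' Builds the fixed-effects design used to regress out SNP main effects
#' before the epistasis screen: for each SNP, two indicator columns
#' (heterozygote and minor-allele homozygote) against the major-homozygote
#' reference. Rows with any missing selected genotype are set to NA so the
#' downstream fit is complete-case. Columns that are constant in the sample
#' (monomorphic SNP, or no heterozygotes) are dropped with a warning to keep
#' the design full rank.
#'
#' @param geno numeric matrix of minor-allele counts in \{0,1,2,NA\}, rows =
#'   individuals (rownames = ids), columns = SNPs (named).
#' @param snps SNP names (or column indices) to encode; default all columns.
#' @return numeric matrix with rows matching \code{geno} and columns
#'   \code{<snp>_het}, \code{<snp>_hom}; attribute \code{"dropped"} lists
#'   removed columns.
#' @examples
#' g <- cbind(SNP1 = c(0, 1, 2, 1))
#' codominant_design(g)
#' @export
codominant_design <- function(geno, snps = colnames(geno)) {
  geno <- as.matrix(geno)
  if (is.numeric(snps)) snps <- colnames(geno)[snps]
  miss <- setdiff(snps, colnames(geno))
  if (length(miss)) stop("SNPs not in genotype matrix: ",
                         paste(miss, collapse = ", "))
  g <- geno[, snps, drop = FALSE]
  if (!all(g %in% c(0, 1, 2, NA)))
    stop("genotypes must be minor-allele counts 0/1/2 or NA")
  incomplete <- rowSums(is.na(g)) > 0L
  cols <- list()
  for (s in snps) {
    cols[[paste0(s, "_het")]] <- as.numeric(g[, s] == 1)
    cols[[paste0(s, "_hom")]] <- as.numeric(g[, s] == 2)
  }
  X <- do.call(cbind, cols)
  rownames(X) <- rownames(geno)
  X[incomplete, ] <- NA_real_
  keep <- apply(X, 2L, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0L && stats::var(v) > 0
  })
  dropped <- colnames(X)[!keep]
  if (length(dropped))
    warning("dropping constant co-dominant columns: ",
            paste(dropped, collapse = ", "))
  X <- X[, keep, drop = FALSE]
  attr(X, "dropped") <- dropped
  X
}

# Connected components of the nonzero pattern of a symmetric matrix;
# used to eigendecompose a family-block-diagonal relationship matrix
# block by block.
matrix_blocks <- function(A, tol = 1e-12) {
  n <- nrow(A)
  comp <- integer(n)
  nz <- abs(A) > tol
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(nz[i, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  split(seq_len(n), comp)
}

# Blockwise symmetric eigendecomposition: values d (length n) and a list of
# per-block eigenvector matrices, so U'x and Ux cost O(sum block^2).
block_eigen <- function(A) {
  blocks <- matrix_blocks(A)
  n <- nrow(A)
  d <- numeric(n)
  vecs <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    ix <- blocks[[b]]
    if (length(ix) == 1L) {
      d[ix] <- A[ix, ix]
      vecs[[b]] <- matrix(1, 1L, 1L)
    } else {
      e <- eigen(A[ix, ix, drop = FALSE], symmetric = TRUE)
      d[ix] <- e$values
      vecs[[b]] <- e$vectors
    }
  }
  list(blocks = blocks, values = d, vectors = vecs)
}

be_crossprod <- function(be, x) {  # U' x  (x vector or matrix)
  x <- as.matrix(x)
  out <- matrix(0, nrow(x), ncol(x))
  for (b in seq_along(be$blocks)) {
    ix <- be$blocks[[b]]
    out[ix, ] <- crossprod(be$vectors[[b]], x[ix, , drop = FALSE])
  }
  out
}

be_prod <- function(be, x) {       # U x
  x <- as.matrix(x)
  out <- matrix(0, nrow(x), ncol(x))
  for (b in seq_along(be$blocks)) {
    ix <- be$blocks[[b]]
    out[ix, ] <- be$vectors[[b]] %*% x[ix, , drop = FALSE]
  }
  out
}

#' Fit the additive polygenic mixed model by maximum likelihood
#'
#' Fits \eqn{y = X\beta + G + e} with \eqn{G \sim N(0, \sigma^2_G A)} and
#' \eqn{e \sim N(0, \sigma^2_E I)}, A the additive relationship matrix, by
#' full maximum likelihood. The likelihood is profiled over the heritability
#' ratio \eqn{\gamma = \sigma^2_G / (\sigma^2_G + \sigma^2_E)} using one
#' eigendecomposition of A (done block by block over family blocks), then
#' maximized in one dimension. Only complete cases (trait and all design
#' columns observed) enter the fit; the relationship matrix should be built
#' from the full pedigree and subset here.
#'
#' Breeding values are empirical BLUPs
#' \eqn{\hat G = \hat\sigma^2_G A \hat V^{-1}(y - X\hat\beta)} and the
#' environmental residuals \eqn{y^* = y - X\hat\beta - \hat G} are free of
#' polygenic familial correlation, ready for association screening.
#'
#' @param y named numeric trait vector (NA = missing).
#' @param A additive relationship matrix with dimnames covering
#'   \code{names(y)}.
#' @param X optional fixed-effects design matrix (rownames = ids); an
#'   intercept column is always added internally. NA rows are dropped
#'   (complete-case).
#' @param min_n minimum number of complete cases (default 10).
#' @return An object of class \code{polygenic_fit}: list with
#'   \code{fixed_effects}, \code{sigma2_g}, \code{sigma2_e}, \code{h2},
#'   \code{breeding_values}, \code{residuals} (full-length named, NA where
#'   incomplete), \code{loglik}, \code{n_used}, \code{boundary} flag.
#' @export
fit_polygenic <- function(y, A, X = NULL, min_n = 10L) {
  if (is.null(names(y))) stop("trait vector must be named by individual id")
  ids <- names(y)
  if (!all(ids %in% rownames(A)))
    stop("relationship matrix does not cover all trait ids")
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (is.null(rownames(X))) {
      if (nrow(X) != length(y)) stop("X rows must align with trait ids")
      rownames(X) <- ids
    }
    if (!all(ids %in% rownames(X))) stop("X rows must cover all trait ids")
    X <- X[ids, , drop = FALSE]
  }
  cc <- !is.na(y)
  if (!is.null(X)) cc <- cc & stats::complete.cases(X)
  n <- sum(cc)
  if (n < min_n) stop("fewer than ", min_n, " complete cases")
  ycc <- y[cc]
  if (stats::var(ycc) == 0) stop("trait is constant over complete cases")
  Xcc <- cbind(`(Intercept)` = rep(1, n),
               if (!is.null(X)) X[cc, , drop = FALSE])
  Acc <- A[ids[cc], ids[cc], drop = FALSE]
  if (max(abs(Acc - t(Acc))) > 1e-8) stop("relationship matrix not symmetric")

  be <- block_eigen(Acc)
  dmin <- min(be$values)
  if (dmin < -1e-6) stop("relationship matrix not positive semi-definite")
  d <- pmax(be$values, 0)
  yt <- drop(be_crossprod(be, ycc))
  Xt <- be_crossprod(be, Xcc)
  colnames(Xt) <- colnames(Xcc)

  profile_ll <- function(gamma) {
    w <- gamma * d + (1 - gamma)
    sw <- sqrt(w)
    fit <- stats::lm.fit(Xt / sw, yt / sw)
    rss <- sum(fit$residuals^2)
    s2 <- rss / n
    ll <- -0.5 * n * log(2 * pi) - 0.5 * n * log(s2) -
      0.5 * sum(log(w)) - 0.5 * n
    list(ll = ll, beta = fit$coefficients, s2 = s2)
  }

  opt <- stats::optimize(function(g) profile_ll(g)$ll,
                         interval = c(0, 1 - 1e-6),
                         maximum = TRUE, tol = 1e-9)
  gamma <- opt$maximum
  at0 <- profile_ll(0)
  # prefer the sigma2_g = 0 boundary when it is not beaten by the interior
  # optimum (resolves the flat profile of singleton-only data deterministically)
  if (at0$ll >= opt$objective - 1e-8) {
    gamma <- 0
    sol <- at0
  } else {
    sol <- profile_ll(gamma)
  }
  boundary <- gamma <= 1e-8
  if (boundary) gamma <- 0

  beta <- sol$beta
  beta[is.na(beta)] <- 0  # rank-deficient guard; design is pre-pruned
  s2_t <- sol$s2
  sigma2_g <- gamma * s2_t
  sigma2_e <- (1 - gamma) * s2_t

  w <- gamma * d + (1 - gamma)
  r0 <- ycc - drop(Xcc %*% beta)
  rt <- drop(be_crossprod(be, r0))
  gt <- (gamma * d / w) * rt
  ghat <- drop(be_prod(be, gt))
  resid_cc <- r0 - ghat

  residuals <- breeding <- stats::setNames(rep(NA_real_, length(y)), ids)
  residuals[cc] <- resid_cc
  breeding[cc] <- ghat

  structure(list(fixed_effects = beta,
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 h2 = gamma,
                 breeding_values = breeding,
                 residuals = residuals,
                 loglik = sol$ll,
                 n_used = n,
                 boundary = boundary,
                 complete = cc),
            class = "polygenic_fit")
}

#' Familial-correlation-free residuals from a polygenic fit
#'
#' Returns \eqn{y^*_i = y_i - (X\hat\beta)_i - \hat G_i} for complete cases
#' and NA elsewhere. These residuals are the trait used in the pair screen
#' and in the permutation null.
#'
#' @param fit a \code{polygenic_fit}.
#' @return named numeric vector.
#' @export
environmental_residuals <- function(fit) {
  stopifnot(inherits(fit, "polygenic_fit"))
  fit$residuals
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat("Polygenic mixed model (ML)\n")
  cat(sprintf("  n used: %d   logLik: %.4f\n", x$n_used, x$loglik))
  cat(sprintf("  sigma2_G: %.4f   sigma2_E: %.4f   h2: %.4f%s\n",
              x$sigma2_g, x$sigma2_e, x$h2,
              if (x$boundary) "   [boundary sigma2_G = 0]" else ""))
  cat("  fixed effects:\n")
  print(round(x$fixed_effects, 4))
  invisible(x)
}
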