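# Two-locus quantitative-trait simulation: nuclear-family pedigrees,
# HWE/LE genotypes with Mendelian transmission, and phenotypes from a
# measured-genotype model with additive polygenic and environmental
# components. Total trait variance is fixed at 1, so the two-locus variance
# fraction g2 and the total heritability h2 determine the variance split:
# sigma2_M = g2, sigma2_G = h2 - g2, sigma2_E = 1 - h2.

#' Hardy-Weinberg genotype frequencies
#'
#' @param p minor allele frequency in (0, 1).
#' @return numeric vector \code{c((1-p)^2, 2p(1-p), p^2)} over minor-allele
#'   counts 0, 1, 2.
#' @export
hwe_genotype_freqs <- function(p) {
  if (!is.numeric(p) || p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  c(`0` = (1 - p)^2, `1` = 2 * p * (1 - p), `2` = p^2)
}

# 0/1 elevation pattern of the two epistasis models over the 3x3 grid.
# M27: elevated iff both loci carry at least one minor allele.
# M170: elevated iff exactly one of the two loci is heterozygous.
model_pattern <- function(model_id) {
  g <- 0:2
  switch(model_id,
         M27 = outer(g, g, function(a, b) as.numeric(a >= 1 & b >= 1)),
         M170 = outer(g, g, function(a, b)
           as.numeric((a == 1) + (b == 1) == 1)),
         stop("unknown model id: ", model_id))
}

#' Genotype-cell means of a two-locus model
#'
#' Builds the 3x3 grid of genotype-specific trait means
#' \eqn{\mu_{jk} = c f(j,k)} where f is the model's 0/1 elevation pattern
#' and the scale c is chosen so the population variance of the means under
#' HWE/LE genotype frequencies equals \code{g2 * sigma2_T}. With
#' \code{g2 = 0} all means are zero.
#'
#' @param model_id \code{"M27"} (elevated iff both loci carry a minor
#'   allele) or \code{"M170"} (elevated iff exactly one locus is
#'   heterozygous).
#' @param p causal minor allele frequency, shared by both loci.
#' @param g2 two-locus variance fraction \eqn{\sigma^2_M / \sigma^2_T}.
#' @param sigma2_T total trait variance (default 1).
#' @return 3x3 numeric matrix indexed by minor-allele counts of locus 1
#'   (rows) and locus 2 (columns).
#' @export
build_model_means <- function(model_id, p, g2, sigma2_T = 1) {
  freqs <- hwe_genotype_freqs(p)
  if (g2 < 0) stop("g2 must be >= 0")
  if (g2 == 0)
    return(matrix(0, 3L, 3L, dimnames = list(0:2, 0:2)))
  f <- model_pattern(model_id)
  W <- outer(freqs, freqs)
  fbar <- sum(W * f)
  vf <- sum(W * (f - fbar)^2)   # Bernoulli variance of the pattern
  cc <- sqrt(g2 * sigma2_T / vf)
  means <- cc * f
  dimnames(means) <- list(0:2, 0:2)
  means
}

#' Closed-form two-locus variance decomposition
#'
#' Decomposes the population variance of a 3x3 genotype-mean grid under
#' HWE/LE frequencies into single-locus main-effect variances and the
#' epistatic remainder:
#' \eqn{\sigma^2_M = \sum_{jk} P_j P_k (\mu_{jk} - \bar\mu)^2},
#' \eqn{\sigma^2_A = \sum_j P_j (\mu_{j\cdot} - \bar\mu)^2} (locus 1
#' marginal means), \eqn{\sigma^2_B} symmetric, and
#' \eqn{\sigma^2_I = \sigma^2_M - \sigma^2_A - \sigma^2_B}.
#'
#' @param means 3x3 genotype-mean matrix.
#' @param p minor allele frequency shared by both loci.
#' @return list with \code{sigma2_M}, \code{sigma2_A}, \code{sigma2_B},
#'   \code{sigma2_I}.
#' @export
variance_decomposition <- function(means, p) {
  stopifnot(is.matrix(means), all(dim(means) == c(3L, 3L)),
            all(is.finite(means)))
  freqs <- hwe_genotype_freqs(p)
  W <- outer(freqs, freqs)
  mbar <- sum(W * means)
  sigma2_M <- sum(W * (means - mbar)^2)
  mj <- drop(means %*% freqs)      # locus-1 marginal means
  mk <- drop(freqs %*% means)      # locus-2 marginal means
  sigma2_A <- sum(freqs * (mj - mbar)^2)
  sigma2_B <- sum(freqs * (mk - mbar)^2)
  list(sigma2_M = sigma2_M, sigma2_A = sigma2_A, sigma2_B = sigma2_B,
       sigma2_I = sigma2_M - sigma2_A - sigma2_B)
}

#' Two-locus model specification
#'
#' Bundles a model's genotype means with its variance split. The total
#' variance is fixed; the polygenic variance is \code{h2 - g2} and the
#' environmental variance \code{1 - h2} (scaled by \code{sigma2_T}).
#'
#' @inheritParams build_model_means
#' @param h2 total heritability (two-locus plus polygenic variance
#'   fraction); must satisfy \code{g2 <= h2 < 1}.
#' @return An object of class \code{two_locus_model}: list with
#'   \code{model_id}, \code{p}, \code{g2}, \code{h2}, \code{sigma2_T},
#'   \code{means}, \code{sigma2_g}, \code{sigma2_e}, \code{decomposition}.
#' @examples
#' spec <- two_locus_model("M27", p = 0.25, g2 = 0.1, h2 = 0.3)
#' spec$decomposition$sigma2_I / spec$decomposition$sigma2_M
#' @export
two_locus_model <- function(model_id, p, g2, h2, sigma2_T = 1) {
  if (g2 > h2) stop("g2 cannot exceed h2")
  if (h2 >= 1) stop("h2 must be below 1")
  means <- build_model_means(model_id, p, g2, sigma2_T)
  dec <- variance_decomposition(means, p)
  if (abs(dec$sigma2_M - g2 * sigma2_T) > 1e-10)
    stop("internal error: model variance does not match g2")
  structure(list(model_id = model_id, p = p, g2 = g2, h2 = h2,
                 sigma2_T = sigma2_T, means = means,
                 sigma2_g = (h2 - g2) * sigma2_T,
                 sigma2_e = (1 - h2) * sigma2_T,
                 decomposition = dec),
            class = "two_locus_model")
}

#' Marginal-additive (no-epistasis) surface of a two-locus model
#'
#' Projects the genotype means onto the additive surface
#' \eqn{\mu'_{jk} = \mu_{j\cdot} + \mu_{\cdot k} - \bar\mu}, which keeps the
#' marginal means but removes all epistatic variance
#' (\eqn{\sigma^2_I = 0}, \eqn{\sigma^2_M' = \sigma^2_A + \sigma^2_B}).
#'
#' @param means 3x3 genotype-mean matrix.
#' @inheritParams variance_decomposition
#' @return 3x3 additive mean matrix.
#' @export
additive_null_means <- function(means, p) {
  freqs <- hwe_genotype_freqs(p)
  mbar <- sum(outer(freqs, freqs) * means)
  mj <- drop(means %*% freqs)
  mk <- drop(freqs %*% means)
  out <- outer(mj, mk, `+`) - mbar
  dimnames(out) <- dimnames(means)
  out
}

#' No-epistasis null model: main effects only, heritability held fixed
#'
#' Replaces the two-locus means with their marginal-additive surface and
#' raises the polygenic variance so that the total heritability stays at
#' \code{h2}: \eqn{\sigma^2_G \leftarrow h^2 - \sigma^2_M'/\sigma^2_T} with
#' \eqn{\sigma^2_M' = \sigma^2_A + \sigma^2_B}. Refused for M170 at
#' p = 0.5, a pure-epistasis scenario whose additive surface is flat.
#'
#' @inheritParams two_locus_model
#' @return A \code{two_locus_model} whose \code{model_id} gets an
#'   \code{"-additive"} suffix.
#' @export
no_epistasis_model <- function(model_id, p, g2, h2, sigma2_T = 1) {
  if (model_id == "M170" && abs(p - 0.5) < 1e-12)
    stop("M170 at p = 0.5 is pure epistasis; no additive null exists")
  full <- two_locus_model(model_id, p, g2, h2, sigma2_T)
  means <- additive_null_means(full$means, p)
  dec <- variance_decomposition(means, p)
  if (abs(dec$sigma2_I) > 1e-10)
    stop("internal error: additive surface has epistatic variance")
  structure(list(model_id = paste0(model_id, "-additive"), p = p,
                 g2 = dec$sigma2_M / sigma2_T, h2 = h2,
                 sigma2_T = sigma2_T, means = means,
                 sigma2_g = h2 * sigma2_T - dec$sigma2_M,
                 sigma2_e = (1 - h2) * sigma2_T,
                 decomposition = dec),
            class = "two_locus_model")
}

#' @export
print.two_locus_model <- function(x, ...) {
  cat(sprintf("Two-locus model %s: p = %g, g2 = %g, h2 = %g\n",
              x$model_id, x$p, x$g2, x$h2))
  cat(sprintf("  sigma2_M = %.4f  sigma2_G = %.4f  sigma2_E = %.4f\n",
              x$g2 * x$sigma2_T, x$sigma2_g, x$sigma2_e))
  d <- x$decomposition
  if (d$sigma2_M > 0)
    cat(sprintf("  main/ M = %.2f  epistatic/ M = %.2f\n",
                d$sigma2_A / d$sigma2_M, d$sigma2_I / d$sigma2_M))
  invisible(x)
}

#' Simulate nuclear-family pedigrees
#'
#' Each family has two founder parents and a number of children drawn from
#' \code{child_probs} over 1, 2, 3 children (default 1/4, 1/2, 1/4, so the
#' expected total is 4 individuals per family).
#'
#' @param n_families number of families (default 250).
#' @param child_probs probabilities of 1, 2, 3 children; must sum to 1.
#' @param seed optional integer seed.
#' @return A \code{fammdr_ped}; ids look like \code{F001_1}.
#' @export
simulate_pedigrees <- function(n_families = 250L,
                               child_probs = c(0.25, 0.5, 0.25),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(child_probs) - 1) > 1e-12)
    stop("child_probs must sum to 1")
  nkids <- sample.int(3L, n_families, replace = TRUE, prob = child_probs)
  fam <- sprintf("F%05d", seq_len(n_families))
  size <- 2L + nkids
  fid <- rep(fam, size)
  member <- sequence(size)
  is_child <- member > 2L
  ped <- data.frame(
    fid = fid,
    iid = paste0(fid, "_", member),
    pat = ifelse(is_child, paste0(fid, "_1"), "0"),
    mat = ifelse(is_child, paste0(fid, "_2"), "0"),
    sex = ifelse(member == 1L, 1L, ifelse(member == 2L, 2L, 0L)),
    stringsAsFactors = FALSE)
  class(ped) <- c("fammdr_ped", "data.frame")
  ped
}

#' Simulate genotypes on a pedigree
#'
#' Founders are drawn i.i.d. from HWE genotype frequencies per SNP;
#' children receive one allele from each parent, chosen uniformly from the
#' parent's two alleles, independently per locus (Mendelian transmission,
#' linkage equilibrium across SNPs).
#'
#' @param ped a pedigree.
#' @param mafs per-SNP minor allele frequencies; names become SNP names
#'   (default \code{SNP1}, ...).
#' @param seed optional integer seed.
#' @return integer matrix of minor-allele counts, rownames = individual ids.
#' @export
simulate_genotypes <- function(ped, mafs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  S <- length(mafs)
  snames <- names(mafs)
  if (is.null(snames)) snames <- paste0("SNP", seq_len(S))
  idx <- seq_len(n); names(idx) <- ped$iid
  fa <- unname(idx[ped$pat]); fa[is.na(fa)] <- 0L
  mo <- unname(idx[ped$mat]); mo[is.na(mo)] <- 0L
  ord <- pedigree_order(ped)
  G <- matrix(0L, n, S, dimnames = list(ped$iid, snames))
  founders <- ord[fa[ord] == 0L & mo[ord] == 0L]
  for (s in seq_len(S))
    G[founders, s] <- stats::rbinom(length(founders), 2L, mafs[s])
  kids <- ord[!(ord %in% founders)]
  for (i in kids) {
    gp <- G[fa[i], ]          # one parent's genotypes across SNPs
    gm <- G[mo[i], ]
    G[i, ] <- stats::rbinom(S, 1L, gp / 2) + stats::rbinom(S, 1L, gm / 2)
  }
  G
}

#' Simulate phenotypes from a two-locus measured-genotype model
#'
#' Each individual's mean is the genotype-cell mean of the model at the two
#' causal SNPs; trait values are drawn per family from a multivariate
#' normal with covariance \eqn{\sigma^2_G A_{fam} + \sigma^2_E I}, families
#' independent.
#'
#' @param spec a \code{two_locus_model}.
#' @param geno genotype matrix (rownames = ids).
#' @param ped pedigree; families taken from \code{ped$fid}.
#' @param causal names or indices of the two causal SNPs (default columns
#'   1 and 2).
#' @param seed optional integer seed.
#' @param A optional precomputed relationship matrix for \code{ped}.
#' @return named numeric trait vector over the pedigree individuals.
#' @export
simulate_phenotypes <- function(spec, geno, ped, causal = c(1L, 2L),
                                seed = NULL, A = NULL) {
  stopifnot(inherits(spec, "two_locus_model"))
  if (!is.null(seed)) set.seed(seed)
  g1 <- geno[ped$iid, causal[1L]]
  g2 <- geno[ped$iid, causal[2L]]
  mu <- spec$means[cbind(g1 + 1L, g2 + 1L)]
  y <- stats::setNames(numeric(nrow(ped)), ped$iid)
  chol_cache <- list()
  fam_rows <- split(seq_len(nrow(ped)), ped$fid)
  for (ix in fam_rows) {
    # relationship block per family: avoids materializing the full matrix
    Af <- if (is.null(A))
      additive_relationship(ped[ix, , drop = FALSE])
    else A[ped$iid[ix], ped$iid[ix], drop = FALSE]
    V <- spec$sigma2_g * Af + spec$sigma2_e * diag(length(ix))
    key <- paste(round(V, 10), collapse = ",")
    L <- chol_cache[[key]]
    if (is.null(L)) {
      L <- tryCatch(chol(V),
                    error = function(e) stop("family covariance for ",
                                             ped$fid[ix[1L]],
                                             " is not positive definite"))
      chol_cache[[key]] <- L
    }
    y[ix] <- mu[ix] + drop(crossprod(L, stats::rnorm(length(ix))))
  }
  y
}

#' Simulate one complete dataset
#'
#' Pedigree, genotypes (two causal slots at the model's MAF plus
#' non-functional SNPs), and phenotypes, as one bundle.
#'
#' @inheritParams simulate_phenotypes
#' @param n_families number of nuclear families (default 250).
#' @param n_snps total SNP count including the two causal slots (default
#'   10).
#' @param maf_other MAF of the non-functional SNPs (default 0.25).
#' @param seed optional integer seed.
#' @return list with \code{ped}, \code{geno}, \code{trait}, \code{A},
#'   \code{spec}.
#' @export
simulate_dataset <- function(spec, n_families = 250L, n_snps = 10L,
                             maf_other = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- simulate_pedigrees(n_families)
  mafs <- stats::setNames(c(spec$p, spec$p, rep(maf_other, n_snps - 2L)),
                          paste0("SNP", seq_len(n_snps)))
  geno <- simulate_genotypes(ped, mafs)
  A <- additive_relationship(ped)
  trait <- simulate_phenotypes(spec, geno, ped, A = A)
  list(ped = ped, geno = geno, trait = trait, A = A, spec = spec)
}

#' Simulation-study design grids
#'
#' The alternative grid crosses 2 models x 3 MAFs x 5 two-locus variance
#' fractions x 3 heritabilities (90 settings); the general null crosses
#' 3 MAFs x 3 heritabilities at g2 = 0 (9 settings); the no-epistasis null
#' crosses the 5 model/MAF combinations with an additive surface (M170 at
#' p = 0.5 excluded as pure epistasis) with 5 variance fractions and 3
#' heritabilities (75 settings).
#'
#' @param type one of \code{"alternative"}, \code{"general_null"},
#'   \code{"no_epistasis"}.
#' @return data frame of settings.
#' @export
experiment_grid <- function(type = c("alternative", "general_null",
                                     "no_epistasis")) {
  type <- match.arg(type)
  p_grid <- c(0.1, 0.25, 0.5)
  g2_grid <- c(0.01, 0.02, 0.03, 0.05, 0.1)
  h2_grid <- c(0.3, 0.5, 0.8)
  switch(type,
    alternative = expand.grid(model = c("M27", "M170"), p = p_grid,
                              g2 = g2_grid, h2 = h2_grid,
                              stringsAsFactors = FALSE),
    general_null = expand.grid(p = p_grid, h2 = h2_grid),
    no_epistasis = {
      mp <- expand.grid(model = c("M27", "M170"), p = p_grid,
                        stringsAsFactors = FALSE)
      mp <- mp[!(mp$model == "M170" & mp$p == 0.5), ]
      g <- merge(mp, expand.grid(g2 = g2_grid, h2 = h2_grid))
      g[order(g$model, g$p, g$g2, g$h2), ]
    })
}
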