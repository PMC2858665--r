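# Permutation-based family-wise significance for the FAM-MDR screen.
#
# The null is the general null of no association: the polygenic-stage residuals are
# exchangeable, so each permutation uniformly shuffles the non-missing
# residuals among their holders while the genotypes stay in place, and the
# full pair screen is recomputed to record the maximum statistic MT.  One
# shuffled vector per replicate is reused across all pairs -- required for a
# valid maxT family-wise null.

# B fresh permutation index columns drawn from the current RNG stream.
perm_index_matrix <- function(n, B) {
  if (B == 0L) return(matrix(integer(0), n, 0L))
  vapply(seq_len(B), function(b) sample.int(n), integer(n))
}

# Shared worker: null MT values for a residual vector against a fixed pair
# structure, in memory-bounded chunks.
null_mt_for <- function(y, pc, Z, perms, cell_alpha, min_cell,
                        chunk = 250L) {
  B <- ncol(perms)
  out <- numeric(B)
  for (start in seq(1L, B, by = chunk)) {
    ix <- start:min(start + chunk - 1L, B)
    Y <- matrix(y[perms[, ix]], nrow = length(y))
    out[ix] <- mbmdr_engine(Y, pc, Z = Z, cell_alpha = cell_alpha,
                            min_cell = min_cell)$mt
  }
  out
}

#' Permutation null distribution of the maximum MB-MDR statistic
#'
#' For each permutation the non-missing residuals are shuffled uniformly
#' (genotypes fixed in place, preserving every pair's available-case
#' subset), the full screen over all pairs and both statistics is
#' recomputed, and the maximum MT is recorded.
#'
#' @param residuals numeric residual trait (NAs excluded from permutation).
#' @param geno genotype matrix aligned with \code{residuals}.
#' @param n_perms number of permutations (1000 recommended).
#' @param seed optional integer seed for reproducibility.
#' @inheritParams mbmdr_label_cells
#' @return numeric vector of \code{n_perms} null MT values.
#' @export
maxt_null <- function(residuals, geno, n_perms = 1000L, seed = NULL,
                      cell_alpha = 0.1, min_cell = 2L) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perms == 0L) return(numeric(0))
  keep <- !is.na(residuals)
  y <- residuals[keep]
  pc <- pair_cell_index(as.matrix(geno)[keep, , drop = FALSE])
  Z <- pair_membership(pc)
  perms <- perm_index_matrix(length(y), n_perms)
  null_mt_for(y, pc, Z, perms, cell_alpha, min_cell)
}

#' Permutation p-value with the add-one convention
#'
#' \eqn{p = (1 + \#\{MT_{null} \ge MT_{obs}\}) / (1 + B)}; never returns 0.
#'
#' @param mt_obs observed maximum statistic.
#' @param null_mt vector of null maximum statistics.
#' @return p-value in (0, 1].
#' @export
adjusted_pvalue <- function(mt_obs, null_mt) {
  if (!length(null_mt)) stop("empty permutation null")
  (1 + sum(null_mt >= mt_obs)) / (1 + length(null_mt))
}

#' Marginal permutation p-value of the best pair (the liberal variant)
#'
#' Permutation significance of the selected pair alone: each permuted
#' residual vector is rescreened for the fixed pair only, maximizing over
#' its two statistics T_H and T_L but not over pairs. This ignores the
#' multiplicity of the pair search and is anti-conservative by construction;
#' it exists for comparison with methods that assess only the selected
#' model. No stopping rule is used.
#'
#' @param best_pair length-2 character vector of SNP names (or 2 indices).
#' @inheritParams maxt_null
#' @return list with \code{p_marginal}, \code{stat_obs}, \code{n_perms}.
#' @export
marginal_pvalue_star <- function(best_pair, residuals, geno,
                                 n_perms = 1000L, seed = NULL,
                                 cell_alpha = 0.1, min_cell = 2L) {
  if (!is.null(seed)) set.seed(seed)
  geno <- as.matrix(geno)
  if (is.character(best_pair)) best_pair <- match(best_pair, colnames(geno))
  if (anyNA(best_pair)) stop("best_pair SNPs not found in genotype matrix")
  keep <- !is.na(residuals)
  y <- residuals[keep]
  pc <- pair_cell_index(geno[keep, best_pair, drop = FALSE])
  Z <- pair_membership(pc)
  obs <- mbmdr_engine(matrix(y, ncol = 1L), pc, Z = Z,
                      cell_alpha = cell_alpha, min_cell = min_cell)$mt
  perms <- perm_index_matrix(length(y), n_perms)
  null_mt <- null_mt_for(y, pc, Z, perms, cell_alpha, min_cell)
  list(p_marginal = adjusted_pvalue(obs, null_mt), stat_obs = obs,
       n_perms = n_perms)
}

#' Sequential maxT permutation test with early stopping
#'
#' Permutations run in batches; after each batch the running p-value
#' estimate \eqn{\hat p = (1 + exceedances) / (1 + m)} is compared with a
#' two-sided binomial (normal-approximation) confidence interval for a
#' proportion \code{alpha} at the current permutation count m. Falling below
#' the interval stops with "significant", above with "not_significant";
#' reaching \code{max_perms} decides by \eqn{\hat p \le alpha}. A stopped
#' run does not provide an accurate p-value estimate, only a decision.
#'
#' @param mt_obs observed maximum statistic from the screen.
#' @inheritParams maxt_null
#' @param alpha significance level (default 0.05).
#' @param batch permutations per batch (default 100).
#' @param max_perms permutation cap (default 1000).
#' @param ci_level confidence level of the stopping interval (default 0.999).
#' @return list with \code{decision} ("significant"/"not_significant"),
#'   \code{n_perms_used}, \code{p_hat} (inaccurate when stopped early),
#'   \code{exceed}, \code{stopped_early}.
#' @export
sequential_permutation <- function(mt_obs, residuals, geno, alpha = 0.05,
                                   batch = 100L, max_perms = 1000L,
                                   ci_level = 0.999, seed = NULL,
                                   cell_alpha = 0.1, min_cell = 2L) {
  if (batch > max_perms) stop("batch size exceeds max_perms")
  if (!is.null(seed)) set.seed(seed)
  keep <- !is.na(residuals)
  y <- residuals[keep]
  pc <- pair_cell_index(as.matrix(geno)[keep, , drop = FALSE])
  Z <- pair_membership(pc)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  exceed <- 0L
  m <- 0L
  repeat {
    b <- min(batch, max_perms - m)
    perms <- perm_index_matrix(length(y), b)
    exceed <- exceed + sum(null_mt_for(y, pc, Z, perms, cell_alpha,
                                       min_cell) >= mt_obs)
    m <- m + b
    p_hat <- (1 + exceed) / (1 + m)
    half <- z * sqrt(alpha * (1 - alpha) / m)
    if (p_hat < alpha - half)
      return(list(decision = "significant", n_perms_used = m, p_hat = p_hat,
                  exceed = exceed, stopped_early = m < max_perms))
    if (p_hat > alpha + half)
      return(list(decision = "not_significant", n_perms_used = m,
                  p_hat = p_hat, exceed = exceed,
                  stopped_early = m < max_perms))
    if (m >= max_perms)
      return(list(decision = if (p_hat <= alpha) "significant"
                  else "not_significant",
                  n_perms_used = m, p_hat = p_hat, exceed = exceed,
                  stopped_early = FALSE))
  }
}

#' Run the full FAM-MDR pipeline
#'
#' Pedigree relationship matrix, polygenic mixed-model fit (optionally
#' adjusting for co-dominant SNP main effects and covariates),
#' familial-correlation-free residuals, MB-MDR screen over all SNP pairs,
#' and permutation significance of the best pair: either a fixed number of
#' permutations (exact maxT p-value) or the sequential early-stopping rule.
#' Optionally also computes the liberal marginal p-value of the best pair.
#' Fully reproducible given \code{seed}.
#'
#' @param trait named numeric quantitative trait vector.
#' @param geno genotype matrix of minor-allele counts (rownames = ids,
#'   colnames = SNP names).
#' @param ped pedigree covering the trait ids (connecting relatives may be
#'   present without phenotype or genotype).
#' @param adjust_snps SNP names whose co-dominant main effects are regressed
#'   out in the polygenic fit (NULL = none).
#' @param covariates optional numeric covariate matrix (rownames = ids).
#' @param alpha significance level (default 0.05).
#' @param n_perms permutations for the fixed-count test and for the marginal
#'   variant (default 1000).
#' @param sequential use the batched stopping rule instead of a fixed count.
#' @param batch,ci_level,max_perms sequential-rule settings (see
#'   \code{\link{sequential_permutation}}); \code{max_perms} defaults to
#'   \code{n_perms}.
#' @param marginal also compute the liberal marginal p-value (FAM-MDR*
#'   style). With a fixed permutation count the same permutation stream is
#'   used for the family-wise and marginal p-values, so
#'   \code{p_adjusted >= p_marginal} holds exactly.
#' @param log_trait natural-log transform the trait before the polygenic fit.
#' @param seed integer seed for the permutation RNG.
#' @inheritParams mbmdr_label_cells
#' @return An object of class \code{fammdr_result}: list with
#'   \code{best_pair}, \code{mt_obs}, \code{p_adjusted} (NA when the
#'   sequential rule stopped early), \code{p_marginal} (optional),
#'   \code{n_perms_used}, \code{decision}, \code{screen}, \code{fit},
#'   \code{seed}.
#' @export
run_fammdr <- function(trait, geno, ped, adjust_snps = NULL,
                       covariates = NULL, alpha = 0.05, n_perms = 1000L,
                       sequential = FALSE, batch = 100L,
                       max_perms = n_perms, ci_level = 0.999,
                       marginal = FALSE, cell_alpha = 0.1, min_cell = 2L,
                       log_trait = FALSE, seed = NULL) {
  geno <- as.matrix(geno)
  if (is.null(names(trait))) {
    if (length(trait) != nrow(geno))
      stop("unnamed trait must align with genotype rows")
    names(trait) <- rownames(geno)
  }
  ids <- names(trait)
  if (is.null(rownames(geno))) rownames(geno) <- ids
  if (!all(ids %in% rownames(geno)))
    stop("genotype matrix does not cover all trait ids")
  geno <- geno[ids, , drop = FALSE]
  if (log_trait) {
    if (any(trait <= 0, na.rm = TRUE))
      stop("log transform requires strictly positive trait values")
    trait <- log(trait)
  }

  A <- additive_relationship(ped, ids = ids)
  X <- NULL
  if (!is.null(adjust_snps))
    X <- codominant_design(geno, adjust_snps)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(rownames(covariates))) rownames(covariates) <- ids
    X <- if (is.null(X)) covariates[ids, , drop = FALSE] else
      cbind(X, covariates[ids, , drop = FALSE])
  }
  fit <- fit_polygenic(trait, A, X)
  resid <- environmental_residuals(fit)
  screen <- mbmdr_screen(resid, geno, cell_alpha = cell_alpha,
                         min_cell = min_cell)

  if (!is.null(seed)) set.seed(seed)
  p_marginal <- NULL
  if (sequential) {
    sq <- sequential_permutation(screen$mt_obs, resid, geno, alpha = alpha,
                                 batch = batch, max_perms = max_perms,
                                 ci_level = ci_level, seed = NULL,
                                 cell_alpha = cell_alpha,
                                 min_cell = min_cell)
    decision <- sq$decision
    n_used <- sq$n_perms_used
    p_adj <- if (sq$stopped_early) NA_real_ else sq$p_hat
    if (marginal)
      p_marginal <- marginal_pvalue_star(screen$best_pair, resid, geno,
                                         n_perms = n_perms, seed = NULL,
                                         cell_alpha = cell_alpha,
                                         min_cell = min_cell)$p_marginal
  } else {
    keep <- !is.na(resid)
    y <- resid[keep]
    pc <- pair_cell_index(geno[keep, , drop = FALSE])
    Z <- pair_membership(pc)
    perms <- perm_index_matrix(length(y), n_perms)
    null_all <- null_mt_for(y, pc, Z, perms, cell_alpha, min_cell)
    p_adj <- adjusted_pvalue(screen$mt_obs, null_all)
    decision <- if (p_adj <= alpha) "significant" else "not_significant"
    n_used <- n_perms
    if (marginal) {
      bp <- match(screen$best_pair, colnames(geno))
      pcm <- pair_cell_index(geno[keep, bp, drop = FALSE])
      Zm <- pair_membership(pcm)
      obs_m <- mbmdr_engine(matrix(y, ncol = 1L), pcm, Z = Zm,
                            cell_alpha = cell_alpha,
                            min_cell = min_cell)$mt
      null_m <- null_mt_for(y, pcm, Zm, perms, cell_alpha, min_cell)
      p_marginal <- adjusted_pvalue(obs_m, null_m)
    }
  }

  structure(list(best_pair = screen$best_pair,
                 mt_obs = screen$mt_obs,
                 p_adjusted = p_adj,
                 p_marginal = p_marginal,
                 n_perms_used = n_used,
                 decision = decision,
                 alpha = alpha,
                 screen = screen,
                 fit = fit,
                 seed = seed),
            class = "fammdr_result")
}

#' @export
print.fammdr_result <- function(x, ...) {
  cat("FAM-MDR result\n")
  cat(sprintf("  best pair: (%s, %s)   MT = %.4f\n",
              x$best_pair[1L], x$best_pair[2L], x$mt_obs))
  cat(sprintf("  decision: %s at alpha = %g (%d permutations)\n",
              x$decision, x$alpha, x$n_perms_used))
  if (!is.na(x$p_adjusted))
    cat(sprintf("  family-wise maxT p-value: %.4g\n", x$p_adjusted))
  else
    cat("  family-wise p-value: not estimated (sequential early stop)\n")
  if (!is.null(x$p_marginal))
    cat(sprintf("  marginal (liberal) p-value: %.4g\n", x$p_marginal))
  invisible(x)
}
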