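# MB-MDR pair screen on familial-correlation-free residuals.
#
# Step 1: for each SNP pair, each of the 9 two-locus genotype cells is tested
# against the other 8 with a pooled-variance two-sample t-test; cells with
# two-sided p below cell_alpha are labeled H (cell mean above the rest) or L
# (below), others O.  Step 2: the merged H cells are tested against their
# complement, and likewise the L cells, giving squared-t Wald statistics
# T_H and T_L.  The engine below evaluates all pairs for many trait vectors
# at once (columns of Y), which is what makes the maxT permutation null
# affordable: cell sums for every pair come from one sparse crossproduct.

# Precompute per-pair cell membership for a genotype matrix. Individuals with
# a missing genotype in a pair are excluded from that pair only (available
# cases); individuals with a missing residual are excluded globally before
# calling this.
pair_cell_index <- function(geno) {
  geno <- as.matrix(geno)
  S <- ncol(geno)
  if (S < 2L) stop("need at least 2 SNPs")
  if (!all(geno %in% c(0, 1, 2, NA)))
    stop("genotypes must be minor-allele counts 0/1/2 or NA")
  pairs <- t(utils::combn(S, 2L))
  P <- nrow(pairs)
  n <- nrow(geno)
  cells <- matrix(NA_integer_, n, P)
  for (k in seq_len(P)) {
    g1 <- geno[, pairs[k, 1L]]
    g2 <- geno[, pairs[k, 2L]]
    cells[, k] <- 3L * g1 + g2 + 1L   # 1..9, row-major in g1
  }
  snames <- colnames(geno)
  if (is.null(snames)) snames <- paste0("SNP", seq_len(S))
  list(pairs = pairs, snp_names = snames, cells = cells, n = n, n_pairs = P)
}

# Sparse 0/1 membership matrix: n x (9 * n_pairs). Column block k holds the
# 9 cells of pair k; rows with missing genotype contribute to no column of
# that block.
pair_membership <- function(pc) {
  P <- pc$n_pairs
  ij <- which(!is.na(pc$cells), arr.ind = TRUE)
  col <- (ij[, 2L] - 1L) * 9L + pc$cells[ij]
  Matrix::sparseMatrix(i = ij[, 1L], j = col,
                       x = 1, dims = c(pc$n, 9L * P))
}

# Pooled-variance squared t for groups summarized by (n1, sum1, sumsq1)
# within a total of (N, S, Q); zero when either group is empty or the mean
# difference is zero; capped at .Machine$double.xmax when the pooled
# variance vanishes with a nonzero mean difference.
pooled_t2 <- function(n1, s1, q1, N, S, Q) {
  s1 <- as.matrix(s1); q1 <- as.matrix(q1)
  dm <- dim(s1)
  conform <- function(x) if (is.matrix(x)) x else matrix(x, dm[1L], dm[2L])
  n1 <- conform(n1); N <- conform(N); S <- conform(S); Q <- conform(Q)
  n2 <- N - n1
  ok <- n1 > 0 & n2 > 0
  m1 <- ifelse(ok, s1 / n1, 0)
  m2 <- ifelse(ok, (S - s1) / pmax(n2, 1), 0)
  md <- m1 - m2
  ssw <- (q1 - ifelse(n1 > 0, s1^2 / pmax(n1, 1), 0)) +
         ((Q - q1) - ifelse(n2 > 0, (S - s1)^2 / pmax(n2, 1), 0))
  ssw <- pmax(ssw, 0)
  sp2 <- ssw / pmax(N - 2, 1)
  denom <- sp2 * (1 / pmax(n1, 1) + 1 / pmax(n2, 1))
  t2 <- ifelse(!ok | md == 0, 0,
               ifelse(denom > 0, md^2 / denom, .Machine$double.xmax))
  list(t2 = t2, meandiff = ifelse(ok, md, 0))
}

# Core screen: Y is an n x B matrix of trait vectors (columns are e.g.
# permutations). Returns per-pair T_H / T_L (P x B), the per-column maximum
# MT, and (when keep_labels) the 9 x P x B H/L masks.
mbmdr_engine <- function(Y, pc, Z = NULL, cell_alpha = 0.1, min_cell = 2L,
                         keep_labels = FALSE) {
  Y <- as.matrix(Y)
  B <- ncol(Y)
  P <- pc$n_pairs
  if (is.null(Z)) Z <- pair_membership(pc)
  counts <- Matrix::colSums(Z)                    # 9P, fixed across columns
  Scell <- as.matrix(Matrix::crossprod(Z, Y))     # 9P x B cell sums
  Qcell <- as.matrix(Matrix::crossprod(Z, Y^2))   # 9P x B cell sums of squares
  pairfac <- rep(seq_len(P), each = 9L)
  Npair <- as.vector(rowsum(counts, pairfac))     # per-pair available n
  Stot <- rowsum(Scell, pairfac)                  # P x B
  Qtot <- rowsum(Qcell, pairfac)
  expand <- function(M) M[pairfac, , drop = FALSE]
  Nrep <- Npair[pairfac]

  ct <- pooled_t2(counts, Scell, Qcell, Nrep, expand(Stot), expand(Qtot))
  dfree <- pmax(Nrep - 2, 1)
  pcell <- 2 * stats::pt(-sqrt(pmin(ct$t2, 1e300)), df = dfree)
  testable <- counts >= min_cell & (Nrep - counts) >= min_cell
  sig <- testable & pcell < cell_alpha
  Hmask <- sig & ct$meandiff > 0
  Lmask <- sig & ct$meandiff < 0

  group_stat <- function(mask) {
    n1 <- rowsum(counts * mask, pairfac)
    s1 <- rowsum(Scell * mask, pairfac)
    q1 <- rowsum(Qcell * mask, pairfac)
    pooled_t2(n1, s1, q1, Npair, Stot, Qtot)$t2
  }
  t_h <- group_stat(Hmask)
  t_l <- group_stat(Lmask)
  mt <- apply(pmax(t_h, t_l), 2L, max)

  out <- list(t_h = t_h, t_l = t_l, mt = mt, n_pair = Npair)
  if (keep_labels) {
    lab <- matrix("O", 9L * P, B)
    lab[Hmask] <- "H"
    lab[Lmask] <- "L"
    out$labels <- lab
    out$cell_counts <- counts
    cm <- Scell / pmax(counts, 1)
    cm[counts == 0, ] <- NA_real_
    out$cell_means <- cm
  }
  out
}

#' Label two-locus genotype cells High / Low / No-evidence
#'
#' Tests each of the nine (g1, g2) genotype cells against all other
#' individuals with a pooled-variance two-sample t-test on the residual
#' trait. Cells significant at \code{cell_alpha} (two-sided) are labeled
#' \code{"H"} if the cell mean exceeds the rest, \code{"L"} if below;
#' everything else (including cells with fewer than \code{min_cell}
#' observations) is \code{"O"}. Individuals missing the residual or either
#' genotype are excluded (available cases).
#'
#' @param residuals numeric trait vector (typically
#'   \code{\link{environmental_residuals}} output).
#' @param g1,g2 genotype vectors in \{0,1,2,NA\} aligned with
#'   \code{residuals}.
#' @param cell_alpha per-cell significance threshold, default 0.1.
#' @param min_cell minimum cell count to be testable, default 2.
#' @return An \code{hlo_partition}: list with \code{labels} (3x3 character),
#'   \code{cell_counts}, \code{cell_means} (3x3, NA for empty cells) and
#'   \code{n_used}.
#' @export
mbmdr_label_cells <- function(residuals, g1, g2, cell_alpha = 0.1,
                              min_cell = 2L) {
  stopifnot(length(residuals) == length(g1), length(g1) == length(g2))
  keep <- !is.na(residuals) & !is.na(g1) & !is.na(g2)
  geno <- cbind(a = g1[keep], b = g2[keep])
  pc <- pair_cell_index(geno)
  eng <- mbmdr_engine(matrix(residuals[keep], ncol = 1L), pc,
                      cell_alpha = cell_alpha, min_cell = min_cell,
                      keep_labels = TRUE)
  dn <- list(g1 = 0:2, g2 = 0:2)
  structure(list(
    labels = matrix(eng$labels[, 1L], 3L, 3L, byrow = TRUE, dimnames = dn),
    cell_counts = matrix(eng$cell_counts, 3L, 3L, byrow = TRUE, dimnames = dn),
    cell_means = matrix(eng$cell_means[, 1L], 3L, 3L, byrow = TRUE,
                        dimnames = dn),
    n_used = sum(keep),
    cell_alpha = cell_alpha, min_cell = min_cell),
    class = "hlo_partition")
}

#' Wald-type pair statistics from an H/L/O partition
#'
#' Computes \eqn{T_H}: the squared pooled-variance t statistic comparing all
#' individuals in H-labeled cells against everyone else in the pair's
#' available-case subset, and \eqn{T_L} analogously for the L cells. Either
#' statistic is 0 when its class (or the complement) is empty.
#'
#' @inheritParams mbmdr_label_cells
#' @param partition optional \code{hlo_partition} from
#'   \code{\link{mbmdr_label_cells}} (recomputed if omitted).
#' @return list with \code{t_h}, \code{t_l}, \code{max_stat}, \code{n_used},
#'   \code{partition}.
#' @export
mbmdr_pair_statistics <- function(residuals, g1, g2, partition = NULL,
                                  cell_alpha = 0.1, min_cell = 2L) {
  if (is.null(partition))
    partition <- mbmdr_label_cells(residuals, g1, g2, cell_alpha, min_cell)
  keep <- !is.na(residuals) & !is.na(g1) & !is.na(g2)
  y <- residuals[keep]
  cell_lab <- partition$labels[cbind(g1[keep] + 1L, g2[keep] + 1L)]
  stat_for <- function(class) {
    in_cls <- cell_lab == class
    n1 <- sum(in_cls)
    drop(pooled_t2(n1, sum(y[in_cls]), sum(y[in_cls]^2),
                   length(y), sum(y), sum(y^2))$t2)
  }
  t_h <- stat_for("H")
  t_l <- stat_for("L")
  list(t_h = t_h, t_l = t_l, max_stat = max(t_h, t_l),
       n_used = partition$n_used, partition = partition)
}

#' Screen all SNP pairs with MB-MDR statistics
#'
#' Evaluates every unordered SNP pair on the residual trait with pair-wise
#' available-case subsetting, and reports the best pair: the argmax of
#' max(T_H, T_L), ties broken lexicographically by SNP index.
#'
#' @param residuals named or plain numeric trait vector; NAs excluded.
#' @param geno genotype matrix (rows aligned with \code{residuals}).
#' @inheritParams mbmdr_label_cells
#' @return An object of class \code{mbmdr_screen}: list with \code{pairs}
#'   (data frame: snp_a, snp_b, n_used, labels as a 9-character H/L/O string
#'   in g1-major order, t_h, t_l, max_stat), \code{best} (row index),
#'   \code{best_pair} (character SNP names) and \code{mt_obs}.
#' @export
mbmdr_screen <- function(residuals, geno, cell_alpha = 0.1, min_cell = 2L) {
  geno <- as.matrix(geno)
  stopifnot(nrow(geno) == length(residuals))
  keep <- !is.na(residuals)
  y <- residuals[keep]
  if (length(unique(y)) < 2L) stop("residual trait is constant")
  pc <- pair_cell_index(geno[keep, , drop = FALSE])
  eng <- mbmdr_engine(matrix(y, ncol = 1L), pc, cell_alpha = cell_alpha,
                      min_cell = min_cell, keep_labels = TRUE)
  P <- pc$n_pairs
  labstr <- vapply(seq_len(P), function(k)
    paste(eng$labels[(k - 1L) * 9L + 1:9, 1L], collapse = ""), "")
  pairs <- data.frame(
    snp_a = pc$snp_names[pc$pairs[, 1L]],
    snp_b = pc$snp_names[pc$pairs[, 2L]],
    n_used = eng$n_pair,
    labels = labstr,
    t_h = eng$t_h[, 1L],
    t_l = eng$t_l[, 1L],
    max_stat = pmax(eng$t_h[, 1L], eng$t_l[, 1L]),
    stringsAsFactors = FALSE)
  best <- which.max(pairs$max_stat)  # first max = lexicographic tie-break
  structure(list(pairs = pairs, best = best,
                 best_pair = c(pairs$snp_a[best], pairs$snp_b[best]),
                 mt_obs = pairs$max_stat[best],
                 cell_alpha = cell_alpha, min_cell = min_cell),
            class = "mbmdr_screen")
}

#' @export
print.mbmdr_screen <- function(x, ...) {
  cat(sprintf("MB-MDR screen: %d pairs, best = (%s, %s), MT = %.4f\n",
              nrow(x$pairs), x$best_pair[1L], x$best_pair[2L], x$mt_obs))
  invisible(x)
}

#' @export
print.hlo_partition <- function(x, ...) {
  cat("H/L/O partition (n =", x$n_used, ")\n")
  print(x$labels)
  invisible(x)
}
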