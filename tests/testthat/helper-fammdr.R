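# Shared fixtures and independent oracles, built in code at test time.

# Four-generation outbred-founder pedigree with one inbred individual (J,
# whose parents are first cousins once removed through sibs E and G).
multigen_pedigree <- function() {
  pedigree(
    fid = "1",
    iid = c("A", "B", "C", "D", "X", "E", "F", "G", "H", "I", "J"),
    pat = c("0", "0", "0", "0", "0", "A", "C", "A", "E", "G", "H"),
    mat = c("0", "0", "0", "0", "0", "B", "D", "B", "F", "X", "I"))
}

# Gene-dropping Monte-Carlo oracle for the additive relationship matrix:
# founders receive unique allele labels, children inherit one random allele
# per parent; A_ij is estimated as half the expected count of IBD allele
# pairs between i and j (and 1 + P(IBD within i) on the diagonal).
gene_drop_relationship <- function(ped, reps = 50000L) {
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$iid
  fa <- unname(idx[ped$pat]); fa[is.na(fa)] <- 0L
  mo <- unname(idx[ped$mat]); mo[is.na(mo)] <- 0L
  ord <- fammdr:::pedigree_order(ped)
  a1 <- matrix(0L, reps, n)
  a2 <- matrix(0L, reps, n)
  nxt <- 0L
  for (i in ord) {
    if (fa[i] == 0L) {
      a1[, i] <- nxt + 1L; nxt <- nxt + 1L
    } else {
      pick <- stats::runif(reps) < 0.5
      a1[, i] <- ifelse(pick, a1[, fa[i]], a2[, fa[i]])
    }
    if (mo[i] == 0L) {
      a2[, i] <- nxt + 1L; nxt <- nxt + 1L
    } else {
      pick <- stats::runif(reps) < 0.5
      a2[, i] <- ifelse(pick, a1[, mo[i]], a2[, mo[i]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$iid, ped$iid))
  for (i in seq_len(n)) for (j in i:n) {
    if (i == j) {
      A[i, i] <- 1 + mean(a1[, i] == a2[, i])
    } else {
      sh <- (a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
            (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])
      A[i, j] <- A[j, i] <- mean(sh) / 2
    }
  }
  A
}

# Straightforward re-implementation of the pair screen for one SNP pair,
# built on stats::t.test only; reference for the vectorized engine.
brute_mbmdr <- function(y, g1, g2, cell_alpha = 0.1, min_cell = 2L) {
  keep <- !is.na(y) & !is.na(g1) & !is.na(g2)
  y <- y[keep]; g1 <- g1[keep]; g2 <- g2[keep]
  lab <- matrix("O", 3L, 3L)
  for (a in 0:2) for (b in 0:2) {
    inc <- g1 == a & g2 == b
    if (sum(inc) < min_cell || sum(!inc) < min_cell) next
    tt <- stats::t.test(y[inc], y[!inc], var.equal = TRUE)
    if (tt$p.value < cell_alpha)
      lab[a + 1L, b + 1L] <- if (diff(rev(tt$estimate)) > 0) "H" else "L"
  }
  cl <- lab[cbind(g1 + 1L, g2 + 1L)]
  stat <- function(class) {
    inc <- cl == class
    if (!any(inc) || all(inc)) return(0)
    unname(stats::t.test(y[inc], y[!inc], var.equal = TRUE)$statistic)^2
  }
  list(labels = lab, t_h = stat("H"), t_l = stat("L"), n_used = length(y))
}

# Gaussian mixed-model log-likelihood evaluated the slow direct way
# (dense solve + log-determinant), profiled over beta and total variance at
# a fixed heritability ratio; grid oracle for the profile optimizer.
direct_profile_ll <- function(y, X, A, gamma) {
  n <- length(y)
  V0 <- gamma * A + (1 - gamma) * diag(n)
  Vi <- solve(V0)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  s2 <- drop(t(r) %*% Vi %*% r) / n
  -0.5 * (n * log(2 * pi) + n * log(s2) +
          as.numeric(determinant(V0)$modulus) + n)
}

# Small null dataset for significance tests (general null: no SNP effects).
quick_null_dataset <- function(n_families = 60L, h2 = 0.3, p = 0.25,
                               seed = 1L, n_snps = 10L) {
  spec <- two_locus_model("M27", p = p, g2 = 0, h2 = h2)
  simulate_dataset(spec, n_families = n_families, n_snps = n_snps,
                   seed = seed)
}
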