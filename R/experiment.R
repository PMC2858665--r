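# Experiment drivers: empirical type-I error and power of the pipeline on
# simulated data, with per-dataset seeds derived from one master seed so
# every report is replayable, plus PP-plot data and plain-TSV readers and
# writers for all interfaces.

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

experiment_report <- function(method, n, rejections, setting) {
  rate <- rejections / n
  data.frame(setting, method = method, n_datasets = n,
             rejections = rejections, rate = rate,
             rate_se = sqrt(rate * (1 - rate) / n),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Empirical type-I error of the epistasis screen
#'
#' Simulates datasets under either the general null (no association:
#' \code{g2 = 0}, polygenic variance \code{h2}) or the no-epistasis null
#' (main effects only: the model's marginal-additive surface with the
#' polygenic variance raised to keep \code{h2} fixed), runs the pipeline on
#' each, and reports the fraction of datasets whose best pair is declared
#' significant. Optionally also reports the liberal marginal variant on the
#' same datasets.
#'
#' @param null_type \code{"general"} or \code{"no_epistasis"}.
#' @param model,p,g2,h2 setting (model/g2 ignored under the general null).
#' @param reps number of simulated datasets.
#' @param correction regress out co-dominant main effects of the two causal
#'   SNP slots in the polygenic fit.
#' @param star also compute the marginal (liberal) rejection rate.
#' @param alpha nominal level (default 0.05).
#' @param sequential use the batched early-stopping permutation rule for
#'   the family-wise test (the marginal variant always uses a fixed
#'   \code{max_perms} permutations).
#' @param max_perms,batch,ci_level permutation settings.
#' @param n_families,n_snps,maf_other dataset shape.
#' @param seed master seed; per-dataset seeds are derived from it.
#' @return data frame with one row per method: setting columns,
#'   \code{n_datasets}, \code{rejections}, \code{rate}, \code{rate_se}.
#' @export
run_type1_experiment <- function(null_type = c("general", "no_epistasis"),
                                 model = "M27", p = 0.1, g2 = 0, h2 = 0.3,
                                 reps = 100L, correction = TRUE,
                                 star = FALSE, alpha = 0.05,
                                 sequential = TRUE, max_perms = 1000L,
                                 batch = 100L, ci_level = 0.999,
                                 n_families = 250L, n_snps = 10L,
                                 maf_other = 0.25, seed = 1L) {
  null_type <- match.arg(null_type)
  spec <- if (null_type == "general")
    two_locus_model(model, p, 0, h2)
  else
    no_epistasis_model(model, p, g2, h2)
  seeds <- derive_seeds(seed, reps)
  rej <- rej_star <- 0L
  for (r in seq_len(reps)) {
    ds <- simulate_dataset(spec, n_families = n_families, n_snps = n_snps,
                           maf_other = maf_other, seed = seeds[r])
    res <- run_fammdr(ds$trait, ds$geno, ds$ped,
                      adjust_snps = if (correction) c("SNP1", "SNP2"),
                      alpha = alpha, n_perms = max_perms,
                      sequential = sequential, batch = batch,
                      max_perms = max_perms, ci_level = ci_level,
                      marginal = star, seed = seeds[r])
    if (res$decision == "significant") rej <- rej + 1L
    if (star && res$p_marginal < alpha) rej_star <- rej_star + 1L
  }
  setting <- data.frame(null_type = null_type, model = spec$model_id,
                        p = p, g2 = g2, h2 = h2, correction = correction,
                        alpha = alpha, seed = seed,
                        stringsAsFactors = FALSE)
  out <- experiment_report("FAM-MDR", reps, rej, setting)
  if (star)
    out <- rbind(out, experiment_report("FAM-MDR*", reps, rej_star, setting))
  out
}

#' Empirical power of the epistasis screen
#'
#' Simulates datasets under a two-locus alternative and reports the
#' fraction in which the correct functional pair (the two causal SNP slots)
#' is both selected as the best pair and declared significant. Ties are
#' only credited when the functional pair wins the deterministic
#' lexicographic tie-break.
#'
#' @inheritParams run_type1_experiment
#' @export
run_power_experiment <- function(model = "M27", p = 0.1, g2 = 0.1,
                                 h2 = 0.3, reps = 100L, correction = TRUE,
                                 star = FALSE, alpha = 0.05,
                                 sequential = TRUE, max_perms = 1000L,
                                 batch = 100L, ci_level = 0.999,
                                 n_families = 250L, n_snps = 10L,
                                 maf_other = 0.25, seed = 1L) {
  spec <- two_locus_model(model, p, g2, h2)
  seeds <- derive_seeds(seed, reps)
  hit <- hit_star <- 0L
  for (r in seq_len(reps)) {
    ds <- simulate_dataset(spec, n_families = n_families, n_snps = n_snps,
                           maf_other = maf_other, seed = seeds[r])
    res <- run_fammdr(ds$trait, ds$geno, ds$ped,
                      adjust_snps = if (correction) c("SNP1", "SNP2"),
                      alpha = alpha, n_perms = max_perms,
                      sequential = sequential, batch = batch,
                      max_perms = max_perms, ci_level = ci_level,
                      marginal = star, seed = seeds[r])
    correct <- setequal(res$best_pair, c("SNP1", "SNP2"))
    if (correct && res$decision == "significant") hit <- hit + 1L
    if (star && correct && res$p_marginal < alpha) hit_star <- hit_star + 1L
  }
  setting <- data.frame(null_type = "alternative", model = model, p = p,
                        g2 = g2, h2 = h2, correction = correction,
                        alpha = alpha, seed = seed,
                        stringsAsFactors = FALSE)
  out <- experiment_report("FAM-MDR", reps, hit, setting)
  if (star)
    out <- rbind(out, experiment_report("FAM-MDR*", reps, hit_star, setting))
  out
}

#' Probability-probability plot coordinates
#'
#' @param pvalues numeric vector of p-values.
#' @return data frame with \code{expected} = i/(n+1) and \code{observed} =
#'   sorted p-values, for plotting observed against expected uniform order
#'   statistics.
#' @export
pp_plot_data <- function(pvalues) {
  if (!length(pvalues)) stop("need at least one p-value")
  n <- length(pvalues)
  data.frame(expected = seq_len(n) / (n + 1), observed = sort(pvalues))
}

# ---- plain-TSV interfaces ---------------------------------------------

#' Read / write genotype and phenotype TSV files
#'
#' Genotype TSV: header row with \code{IID} then SNP names; values 0/1/2/NA
#' (minor-allele counts). Phenotype TSV: header row with \code{IID} then
#' the trait and any covariates; missing = NA.
#'
#' @param path file path.
#' @return \code{read_genotypes}: numeric matrix with ids as rownames;
#'   \code{read_phenotypes}: data frame with \code{IID} column.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(IID = "character"),
                          check.names = FALSE)
  G <- as.matrix(df[, -1L, drop = FALSE])
  rownames(G) <- df$IID
  storage.mode(G) <- "double"
  G
}

#' @rdname read_genotypes
#' @param geno genotype matrix to write.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(IID = rownames(geno), geno, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_genotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(IID = "character"), check.names = FALSE)
}

#' @rdname read_genotypes
#' @param pheno data frame with an \code{IID} column.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read an experiment report as TSV (lossless round trip)
#'
#' @param report a data frame from \code{\link{run_type1_experiment}} or
#'   \code{\link{run_power_experiment}}.
#' @param path file path.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(method = "character",
                                   model = "character",
                                   null_type = "character"))
}

#' Write the per-pair screen table as TSV
#'
#' Columns: snp_a, snp_b, n_used, labels (9-character row-major H/L/O
#' string), t_h, t_l, max_stat.
#'
#' @param screen an \code{mbmdr_screen}.
#' @param path file path.
#' @export
write_screen <- function(screen, path) {
  utils::write.table(screen$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
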