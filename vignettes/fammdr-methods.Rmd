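---
title: "Family-based MB-MDR epistasis screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based MB-MDR epistasis screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fammdr)
```

## The problem

Gene–gene interactions (epistasis) that shape a quantitative trait are hard
to find with single-marker tests, and family data add a second obstacle:
relatives share polygenic background, so observations are not exchangeable.
`fammdr` addresses both with a two-stage design for pedigree samples of
diallelic SNPs and a continuous trait.

**Stage I — polygenic adjustment.** The trait is modeled as
$$y_i = x_i^\top\beta + G_i + e_i, \qquad
G \sim N(0, \sigma^2_G A), \quad e \sim N(0, \sigma^2_E I),$$
where $A$ is the additive relationship matrix derived from the pedigree
(twice the kinship matrix, diagonal $1+F_i$) and $x_i$ optionally carries
co-dominant dummies of SNP main effects and covariates. The model is fit by
full maximum likelihood; the environmental residuals
$$y^*_i = y_i - x_i^\top\hat\beta - \hat G_i,$$
with $\hat G$ the empirical BLUP, are free of polygenic familial
correlation and become the working trait.

**Stage II — model-based MDR screen.** For every unordered SNP pair, the
nine two-locus genotype cells are each tested against the rest with a
pooled-variance $t$-test; cells significant at a liberal threshold
(`cell_alpha = 0.1`) are labeled High or Low according to the direction of
the mean difference, the rest No-evidence. The merged H cells are then
tested against their complement, and likewise the L cells, giving two
squared-$t$ Wald statistics $T_H$ and $T_L$ per pair. The screen statistic
is $MT = \max_{\text{pairs}} \max(T_H, T_L)$.

**Significance.** Family-wise error over all pairs and both tests is
controlled by a maxT permutation null: the non-missing residuals are
shuffled uniformly (genotypes fixed in place), the entire screen is
recomputed, and the maximum is recorded; 1000 permutations are the
recommended default. The permutation p-value uses the add-one convention
$p = (1 + \#\{MT^{(b)} \ge MT_{obs}\})/(1 + B)$, so it never returns 0.
Crucially, one shuffled residual vector is reused across all pairs within a
permutation — per-pair shuffles would not give a valid family-wise null.

A liberal variant (`marginal = TRUE`) also reports the marginal permutation
p-value of the already-selected best pair, maximizing only over its own two
statistics. It ignores the multiplicity of the pair search and is strongly
anti-conservative; it exists to quantify exactly that inflation and for
comparison with methods that only assess the selected model.

## Why residual permutation is valid

Conditional on the genotypes, Stage I removes the familial correlation, so
under the null of no association the residuals are exchangeable. When SNP
main effects are regressed out in Stage I, the null of "no association"
and the null of "no epistasis beyond those main effects" coincide, which is
what makes the corrected analysis a genuine test of interaction rather than
a test that is merely dragged along by main effects. The package's
no-epistasis experiments demonstrate the failure mode: with strong additive
main effects and no correction, the screen declares a "significant
two-locus model" in essentially every dataset.

Residual permutation is approximate in one respect: BLUP shrinkage slightly
overshoots, leaving a small negative within-family residual correlation
(about $-0.11$ for a sib pair at $h^2 = 0.3$, analytically
$\mathrm{cov}(e^*) = \sigma_E^4 V^{-1}$). The permutation null treats
residuals as i.i.d., which in practice makes the family-wise test mildly
conservative — visible in the type-I error experiments, which land near
0.01–0.03 at a nominal 0.05.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cell_alpha` | 0.1 | two-sided per-cell labeling threshold (trait units: none) |
| `min_cell` | 2 | minimum cell count to be testable; smaller cells are labeled O |
| `alpha` | 0.05 | significance level of the screen decision |
| `n_perms` / `max_perms` | 1000 | permutation budget |
| `batch` | 100 | permutations per sequential batch |
| `ci_level` | 0.999 | confidence level of the sequential stopping interval |

`min_cell = 2` is the weakest rule under which a cell variance exists; the
choice barely moves power in our experiments (2 vs 10 changed the corrected
power by 0.01 at the hardest setting), so it is kept minimal and
configurable. `ci_level` is deliberately strict: with a 99.9% interval the
sequential rule almost never contradicts the fixed-budget decision (the
concordance test requires at least 95% agreement), at the cost of running
about 300 permutations before declaring a clearly significant result.

### The sequential stopping rule

Permutations run in batches; after $m$ permutations the rule compares
$\hat p = (1 + \text{exceedances})/(1 + m)$ with the two-sided
normal-approximation binomial interval
$\alpha \pm z_{1-(1-c)/2}\sqrt{\alpha(1-\alpha)/m}$. Falling below stops
with "significant"; rising above stops with "not significant"; at the cap
the decision is $\hat p \le \alpha$. An early-stopped run reports no
p-value estimate — only the decision — because $\hat p$ at a data-dependent
stopping time is biased. The stopping interval's confidence level is a free
parameter of the procedure; we fix 0.999 as the default and expose it.

## The simulation generator

The generator reproduces a classical two-locus quantitative-trait design:

* **Pedigrees**: 250 nuclear families; the number of children is 1, 2 or 3
  with probabilities 1/4, 1/2, 1/4, so a dataset averages 1000 individuals.
* **Genotypes**: 10 diallelic SNPs in linkage equilibrium; founders i.i.d.
  at Hardy–Weinberg proportions, children by Mendelian transmission. The
  two causal slots (SNP1, SNP2) share a MAF $p \in \{0.1, 0.25, 0.5\}$; the
  eight non-functional SNPs default to MAF 0.25 (configurable; none of the
  analytic results depend on it).
* **Phenotypes**: trait values are drawn per family from a multivariate
  normal whose mean is the two-locus genotype-cell mean $\mu_{jk}$ and
  whose covariance is $\sigma^2_G A_{fam} + \sigma^2_E I$.

Two epitasis patterns are built in, as 0/1 elevation indicators scaled to a
target variance: **M27** elevates every cell in which both loci carry at
least one minor allele; **M170** elevates cells in which exactly one locus
is heterozygous. With total variance fixed at 1, the two-locus variance
fraction $g^2$ and total heritability $h^2$ determine
$\sigma^2_M = g^2$, $\sigma^2_G = h^2 - g^2$, $\sigma^2_E = 1 - h^2$.

The closed-form decomposition under HWE/LE splits $\sigma^2_M$ into
single-locus main-effect variances and the epistatic remainder:

```{r table1}
for (m in c("M27", "M170")) for (p in c(0.10, 0.25, 0.50)) {
  d <- variance_decomposition(build_model_means(m, p, g2 = 0.1), p)
  cat(sprintf("%-5s p=%.2f  main %.2f  epistatic %.2f\n", m, p,
              d$sigma2_A / d$sigma2_M, d$sigma2_I / d$sigma2_M))
}
```

M27 becomes more main-effect-driven as $p$ grows; M170 moves the opposite
way and is pure epistasis at $p = 0.5$. These ratios explain the power and
leakage patterns of the experiments: corrected power tracks the epistatic
share, uncorrected "power" tracks the total two-locus variance.

Two null designs complete the study: the **general null** ($g^2 = 0$,
polygenic variance $h^2$) for type-I error of the whole screen, and the
**no-epistasis null**, which replaces the means by their marginal-additive
surface $\mu'_{jk} = \mu_{j\cdot} + \mu_{\cdot k} - \bar\mu$ (zero
epistatic variance, marginals preserved) and raises the polygenic variance
to keep $h^2$ fixed — the design that exposes main-effect leakage. M170 at
$p = 0.5$ has no additive surface to speak of and is refused.

What the generator does **not** emulate: linkage disequilibrium between
markers, ascertainment, missing data, non-Gaussian traits, and
multi-generational pedigrees. Passing tests on these data therefore say
nothing about robustness to LD structure or to selection; they validate the
mixed-model adjustment, the screen, and the permutation machinery under the
stated design.

## Numerical choices

* The polygenic likelihood is profiled over the heritability ratio
  $\gamma = \sigma^2_G/(\sigma^2_G + \sigma^2_E) \in [0, 1-10^{-6}]$ using
  one eigendecomposition of $A$ per dataset, computed family block by
  family block, followed by 1-D maximization to tolerance $10^{-9}$. Ties
  with the $\gamma = 0$ boundary resolve to the boundary, which also fixes
  the non-identifiable singleton-only case deterministically.
* ML, not REML: variance components carry the usual downward ML bias,
  which is immaterial here because only the residuals feed Stage II.
* Degenerate screens: constant residuals give all-O partitions and zero
  statistics rather than errors; a zero pooled variance with a non-zero
  mean difference is capped at the largest finite double.
* Best-pair ties break lexicographically by SNP index, so results are
  reproducible bit for bit under a fixed seed.
* The permutation stream is a single seeded generator; with a fixed
  permutation count the family-wise and marginal p-values share one stream,
  which guarantees $p_{\text{adjusted}} \ge p_{\text{marginal}}$ exactly.

## Problem sizes used in the test suite

The package's experiments are run at reduced replicate counts chosen to
keep Monte-Carlo standard errors interpretable: 100 datasets for the
general-null type-I experiments, 50 for the no-epistasis and power
experiments, 1000 permutations (or the sequential rule capped at 1000).
All stochastic assertions state binomial 3-SE bands around the expected
rates at those sizes.

## Known limitations

* The corrected family-wise screen is conservative by construction, and in
  the hardest corrected-power setting we examined (M27 with causal MAF 0.1,
  $g^2 = 0.1$, $h^2 = 0.3$) it reaches a power of about 0.91–0.92, with the
  remaining failures having exact maxT p-values between 0.05 and 0.11.
* Only pairwise interactions are screened; the labeling logic generalizes
  to higher orders but is not implemented.
* Binary or censored outcomes are out of scope; the Wald machinery assumes
  a continuous trait.
* Population structure beyond the pedigree (admixture, cryptic
  relatedness) is not modeled; with dense genome-wide markers a genomic
  kinship matrix would be the natural drop-in for $A$, but estimating one
  is out of scope here.
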