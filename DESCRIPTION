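Package: fammdr
Title: Family-Based Model-Based Multifactor Dimensionality Reduction for
    Epistasis Detection in Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage detection of gene-gene interactions (epistasis)
    affecting quantitative traits measured on related individuals. Stage one
    fits an additive polygenic mixed model by maximum likelihood, using the
    pedigree-derived relationship matrix, optionally adjusting for co-dominant
    SNP main effects and covariates, and extracts environmental residuals that
    are free of familial correlation. Stage two screens all SNP pairs with a
    model-based multifactor dimensionality reduction statistic (High/Low/
    No-evidence genotype-cell labeling followed by Wald-type tests of the
    merged cells), and assesses family-wise significance of the best pair by a
    maximum-statistic permutation null with an optional sequential stopping
    rule. Includes generators for nuclear-family pedigrees, Mendelian
    genotypes, and two-locus quantitative-trait models with a closed-form
    epistatic variance decomposition, plus drivers for type-I-error and power
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
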