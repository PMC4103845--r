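Package: famtpm
Title: Family-Based Association Tests with Truncated-Product Gene and
    Gene-Family Combination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint-association analysis for quantitative traits in multiplex
    pedigrees. Implements single-SNP family-based association tests (FBAT-type
    score statistics conditioning on parental genotypes) on covariate-adjusted,
    log-transformed traits; combines SNP-level p-values into gene-level and
    gene-family-level evidence with the weighted truncated product method,
    calibrated by a Monte Carlo null that respects linkage disequilibrium; and
    controls multiple testing with Storey q-values. Includes a pedigree
    gene-drop simulator (founder haplotypes with block LD via latent Gaussian
    thresholding, Mendelian transmission with recombination, covariate-driven
    right-skewed traits with family random effects) so the whole pipeline is
    testable end to end with known ground truth, plus readers and writers for
    PLINK-style text PED/MAP files and phenotype/covariate tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
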