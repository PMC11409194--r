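Package: pqtlscreen
Title: Multi-Stage Screening of Protein Quantitative Trait Loci in
    Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links protein quantitative trait loci (pQTL-SNPs) to disease
    risk in case-control designs through a multi-stage screen: differential
    protein expression tested separately in plasma (unpaired) and tissue
    (paired) and intersected with a direction-consistency requirement;
    cis-window, minor-allele-frequency and linkage-disequilibrium filters
    on merged pQTL catalogs; per-SNP association under codominant,
    dominant, recessive and additive genetic models with crude
    cross-product and covariate-adjusted logistic odds ratios; an
    effect-direction concordance classifier that retains biologically
    plausible candidate SNPs; and ROC/AUC evaluation of single and
    combined protein markers. A synthetic-cohort generator with
    Hardy-Weinberg genotypes, block-wise linkage disequilibrium and a
    logistic disease model makes every stage testable without access to
    restricted cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
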