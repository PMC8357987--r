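Package: omicscores
Title: Methylation and Polygenic Score Prediction in Twin Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds DNA-methylation scores (MS) and polygenic scores (PGS)
    from discovery EWAS/GWAS summary statistics, with p-value thresholding,
    greedy correlation pruning and allele alignment; fits nested prediction
    models with family-clustered generalized estimating equations
    (exchangeable working correlation, robust sandwich standard errors); and
    decomposes trait variance into MS and PGS contributions on the observed
    scale for continuous traits and on the liability scale for binary traits.
    Includes a synthetic twin-cohort generator (MZ/DZ genotype sharing,
    correlated CpG blocks, cell-composition confounding, liability-threshold
    traits) with known ground truth so every stage is testable without
    access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    vcfR
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
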