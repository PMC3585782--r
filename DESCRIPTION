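Package: tohkit
Title: Tracts of Homozygosity, Surrogate-TOH Regions and Case-Control
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects per-subject tracts of homozygosity (TOH) from
    PLINK-style ped/map SNP genotypes, aggregates them into surrogate-TOH
    regions -- common (cTOH), positionally grouped (gTOH) and
    allelically matched (aTOH) -- using per-SNP accumulation and a
    repeated binary normalized spectral clustering tree, and tests
    region presence against case-control status with Fisher's exact
    test or covariate-adjusted logistic regression. Includes
    parameter-calibration utilities (chance-run length, LD-adjusted run
    size, empirical tract-length quantiles) and a synthetic genotype
    generator with planted homozygous tracts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
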