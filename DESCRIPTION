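Package: ftlchiasma
Title: Sex-Specific Meiotic Crossover Rates from Fluorescent Tagged Line Seed Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and simulation tools for heterochiasmy studies that
    score meiotic recombination with two-marker fluorescent tagged lines (FTLs)
    in Arabidopsis. Provides a gamma-renewal meiosis simulator with crossover
    interference and seed-class multinomial sampling; recombination-frequency
    estimation and male:female crossover-rate (mCO:fCO) summaries under
    explicit aggregation conventions; Gaussian linear modelling of parental-age
    effects with single-step max-|t| multivariate-t family-wise adjustment;
    quantification of the two-marker non-detection bias for even crossover
    counts; and interval-level prediction of sex-specific crossover rates from
    location-based recombination landscapes, including overlap with
    subtelomeric and pericentromeric zones.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    dplyr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
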