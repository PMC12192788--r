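Package: rohscan
Title: Runs of Homozygosity and Heterozygosity in SNP-Array Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and analysis of runs of homozygosity (ROH) and
    heterozygosity-rich regions (ROHet) in multi-population SNP-array
    genotype data using the consecutive-SNP scanning method. Provides
    PLINK PED/MAP text input and output, a quality-control cascade
    (sample call rate, SNP missingness, minor allele frequency,
    per-population exact Hardy-Weinberg tests), run detection under
    parameterised rule sets, per-animal and per-population length-class
    summaries, genomic inbreeding (F_ROH) and heterozygosity coverage
    (D_ROHet) coefficients, ROH-island (hotspot) calling with
    annotation-interval overlap, nonparametric between-population
    comparisons, and a simulator producing genotype cohorts with known
    autozygosity from planted tracts or pedigree gene-drop with
    recombination.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    S4Vectors,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
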