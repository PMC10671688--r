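Package: rohscan
Title: Runs-of-Homozygosity Detection, Genomic Inbreeding and ROH Islands
    for SNP-Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for runs-of-homozygosity (ROH) analysis of diploid
    SNP-chip genotypes: PLINK-dialect PED/MAP input and output, marker and
    sample quality control (call rate, missingness, minor allele frequency,
    exact Hardy-Weinberg test), sliding-window ROH detection, length-class
    descriptive statistics, F_ROH genomic inbreeding coefficients, and
    top-1% ROH-island detection with gene annotation. Includes a synthetic
    population generator that plants autozygous tracts of known extent so
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
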