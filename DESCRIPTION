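Package: selfpath
Title: SNP-Based Tracking and Acceleration of Homozygosity in Selfed Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for marker-assisted development of inbred lines in
    outcrossing tree crops by regular self-pollination monitored with
    genome-wide SNP genotypes. Reads AB-coded genotype matrices and selfing
    pedigrees, applies marker- and sample-level quality control, computes
    per-individual genotypic counts and observed homozygosity, tests each
    selfed offspring against Mendelian expectations (heterozygous calls
    halve each generation) with a chi-square test, standardizes and ranks
    offspring within families for advancement, verifies parent-offspring
    compatibility under selfing, summarizes cohorts (Hardy-Weinberg tests,
    minor allele frequencies, inbreeding coefficient), and prioritizes
    crosses with Smouse-Peakall codominant genetic distances, UPGMA
    dendrograms, and expected F1 heterozygosity. A synthetic-data module
    simulates selfing series and compares marker-assisted versus random
    advancement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
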