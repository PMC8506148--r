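Package: cpgxeval
Title: Evaluation of Combinatorial Pharmacogenomic Test Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate combinatorial pharmacogenomic (CPGx) test
    panels against cytochrome P450 star-allele diversity. Translates CYP
    diplotypes to genotype-predicted phenotypes, classifies altered-metabolizer
    status from CPIC-derived per-gene rules, and computes per-test, per-gene,
    per-population variant coverage percentages and detection rates from
    PharmGKB-style allele or diplotype frequency tables. Includes a
    Hardy-Weinberg diplotype expansion, a seeded synthetic-data generator
    emulating multi-population star-allele frequency tables, an independent
    brute-force enumeration oracle, and heatmap/prevalence graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    jsonlite,
    ggplot2,
    patchwork,
    rlang,
    withr,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
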