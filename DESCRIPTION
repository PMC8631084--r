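Package: swampx
Title: Sex-Biased Admixture Inference from Autosomal and X-Chromosomal
    f-Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting sex-biased admixture between populations
    from genotype data. Computes f2, outgroup-f3 and f4 statistics with
    weighted block-jackknife standard errors, contrasts f4 on autosomes
    against the X chromosome with Welch's t-test (the nuclear-swamping
    test), fits admixture graphs to f-statistics and refits admixture
    proportions on X-linked data with a fixed topology, builds
    neighbor-joining trees from identity-by-state distances, and ships a
    sex-structured Wright-Fisher allele-frequency simulator that generates
    autosomal, X-linked and mitochondrial genotypes under sex-specific
    pulse and continuous migration.
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
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
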