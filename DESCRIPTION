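Package: editomer
Title: Comparative A-to-I RNA Editome Analysis from RNA and Exome Pileups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects A-to-I RNA editing sites (read out as A>G, or T>C on the
    minus strand) from per-animal RNA-seq base-count pileups while masking
    germline variation called from whole-exome pileups, applies
    all-replicate consensus rules at site and gene level, annotates sites
    against genomic features (5'UTR/CDS/intron/3'UTR/intergenic) and repeat
    elements (SINE/LINE/DNA transposon/other retrotransposon), and compares
    editomes across genotypes via unique sets, four-way Venn partitions,
    percent changes, and interferon-stimulated-gene proportion tests. A
    seeded synthetic-data generator with analytic binomial detection
    oracles makes every stage verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
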