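Package: defmine
Title: Mining and Comparative Analysis of Beta-Defensin Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Motif-constrained discovery of beta-defensin loci in genomic
    sequence (six-frame translation, six-cysteine motif scanning, homology
    screening, gene-model construction under the GT-AG splice rule),
    ortholog-based gene naming from neighbor-joining phylogenies under JTT
    distances, cross-species synteny-cluster comparison, and coding-SNP
    characterization with PCR-RFLP assay design and in-silico PCR. Includes
    a seeded synthetic-genome and population generator with recorded ground
    truth, plus machine-readable encodings of the published pig beta-defensin
    tables, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vcfR,
    withr,
    optparse,
    jsonlite,
    BiocGenerics
Config/testthat/edition: 3
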