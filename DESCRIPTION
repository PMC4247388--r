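Package: orthoscan
Title: Ortholog Sets, Lineage-Unique Residue Scanning and Thresholded
    Differential Expression for Comparative Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-species comparative transcriptomics built
    around four stages: extraction and validation of a representative
    open reading frame per gene, construction of one-to-one ortholog
    sets by reciprocal best hit with start/stop and length refinement
    filters, detection of alignment columns where a focal lineage
    carries an amino acid whose chemical class (acidic, basic, cysteine,
    other) is absent from all other species, and differential-expression
    calling under a triple threshold on log2 fold-change,
    Benjamini-Hochberg adjusted P-value and the B (log posterior odds)
    statistic, with term fold-enrichment by Fisher's exact test. A
    seed-deterministic synthetic-data generator evolves coding sequences
    along a phylogeny, plants lineage-unique substitutions and corrupted
    transcripts, and simulates negative-binomial count matrices, so that
    every stage is testable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    edgeR,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
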