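Package: satkit
Title: Satellitome Characterization from Low-Coverage Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for characterizing the satellite DNA complement
    (satellitome) of a genome from low-coverage paired-end reads. Provides a
    graph-based read-clustering stage that discovers tandem-repeat families,
    monomer extraction and rotation-aware consensus building, RepeatMasker-style
    abundance and Kimura 2-parameter divergence quantification with repeat
    landscapes, minimum spanning networks of subfamilies, assembly scans with a
    90/90 acceptance rule and subfamily co-occurrence matrices, and CPM-based
    classification of satellite transcription patterns across RNA-seq samples.
    A synthetic-data module generates genomes, reads and RNA-seq libraries with
    known ground truth so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    readr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
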