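Package: phytasp
Title: Screening and Characterization of Plant Subtilases and Phytaspases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy toolkit for identifying and characterizing phytaspases,
    the Asp-specific subtilisin-like serine proteases (subtilases, SBTs)
    implicated in plant programmed cell death.  Provides domain-architecture
    screening of proteomes by local alignment against S8/I9 reference
    anchors with a completeness filter, prodomain-junction calling and
    Asp-P1 / S1-pocket residue classification of phytaspase candidates,
    positional amino-acid enrichment statistics behind sequence logos,
    neighbor-joining phylogenies with subfamily assignment and tandem
    gene-array detection, in-silico PICS (proteomic identification of
    cleavage sites) simulation and cleavage-site reconstruction,
    quantification of fluorogenic-substrate kinetics and of necrotic leaf
    area from scanned images, and seeded synthetic-data generators so the
    whole pipeline is testable offline with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
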