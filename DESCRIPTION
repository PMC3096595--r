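Package: netfootprint
Title: Phylogenetic Network Footprinting of Transcription Factor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers and compares transcription-factor (TF) interaction
    networks across species by phylogenetic network footprinting. Proteins
    are classified as TFs by the presence of sequence-specific DNA-binding
    Pfam domains; experimentally verified TF-TF interactions are transferred
    to other species as interologs through ortholog-group cross products;
    per-species networks are aligned into interaction classes to extract
    conserved interactions, conserved subnetworks, taxonomically restricted
    interactions and lineage-specific expansions. Also provides
    domain-composition profiling with the arcsine-square-root transform,
    Fisher contingency tests and domain-composition trees, degree
    distributions with discrete maximum-likelihood power-law fits, a
    six-frame ORF finder with best-hit CDS selection, readers for FASTA,
    InterProScan TSV and Inparanoid sqltable formats, and a ground-truthed
    synthetic-data generator covering every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
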