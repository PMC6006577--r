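Package: mrsbreak
Title: MAR/SAR Motif Scanning and Inverse-PCR Chromosome Break Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate matrix/scaffold attachment regions (MAR/SAR)
    in a gene-local reference by scanning for the bipartite MAR/SAR
    recognition signature (MRS): an exact 8 bp degenerate element (AATAAYAA)
    paired with a 16 bp degenerate element (AWWRTAANNWWGNNNC, one mismatch
    allowed) within a bounded distance on either strand and in either order.
    Simulates the nested inverse-PCR (IPCR) assay used to detect apoptotic
    chromosome breaks (restriction digestion, Klenow fill-in, circularisation,
    secondary-digest selection, nested amplification), maps breakpoints and
    shift-translocation junctions (including junction microhomology) from
    amplicon read sequences, and quantifies gene cleavage frequencies from
    replicate band counts. Includes a synthetic-data generator that emulates
    the wet-lab inputs with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    BiocGenerics,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
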