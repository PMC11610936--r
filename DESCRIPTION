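Package: ttract
Title: DNA-Directed (T-Tract) RNA Polymerase II Termination from RNA 3' End Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects DNA-directed transcription termination of RNA polymerase II
    at T-rich coding-strand elements from stranded single-nucleotide RNA 3'-end
    count tracks across factor-depletion conditions (exosome, XRN2, Integrator).
    Provides per-base CPM normalisation and log2 fold-change tracks, stabilised
    3'-end calling, terminal k-mer motif enrichment with genomic background
    correction, T-run location and distance-binned meta-analysis, region-level
    transcription-unit selection filters, scaled metagene profiles, and a
    stochastic simulator of nascent transcription and termination that generates
    complete desk-scale input bundles (FASTA, BED, bedGraph, manifest) with
    ground truth for every planted signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomeInfoDb,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
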