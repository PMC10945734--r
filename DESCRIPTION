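Package: ribote
Title: Translational Efficiency and uORF Analysis for Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream quantitative analysis of yeast ribosome profiling
    experiments with genotype-by-treatment designs. Computes per-gene
    translational efficiency (TE) from ribosome-protected-fragment and
    RNA-seq count matrices, tests TE changes between conditions with a
    negative-binomial interaction model and Benjamini-Hochberg FDR,
    quantifies upstream open reading frame (uORF) relative ribosome
    occupancy (RRO), scores tripeptide-specific elongation pauses from
    shifted footprint tracks, classifies genes whose translation depends
    conditionally on an initiation factor, and reconstructs per-mRNA TE
    from polysome-gradient qPCR measurements. Includes a synthetic-data
    module that generates annotations, counts, footprint tracks and
    gradient fixtures with known ground truth so every stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    yaml,
    withr,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
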