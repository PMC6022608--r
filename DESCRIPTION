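Package: binbench
Title: Comparative Assessment of Metagenome Genome Binnings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates genome binnings of metagenome benchmark datasets
    against a gold-standard sequence-to-genome assignment. Reads and writes
    the Bioboxes binning format, indexes sequence lengths from FASTA/FASTQ,
    builds the bin-by-genome contingency structure, and computes the
    community-standard quality metrics: per-bin purity, contamination and
    completeness, macro-averaged and truncated averages, base-pair-weighted
    purity and completeness, sample-wide accuracy, and the adjusted Rand
    index of the assigned portion in base-pair and per-sequence currencies.
    Emits comparative flat-file reports, rankings, genome recovery tables,
    ordered confusion-matrix heat maps, plot data and a static HTML summary,
    and ships a seeded synthetic gold-standard and binning-degradation
    generator for testing and calibration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ggplot2,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
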