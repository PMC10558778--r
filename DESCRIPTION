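Package: isomiRq
Title: IsomiR Classification and Quantitation for Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Classifies small RNA-seq reads into canonical microRNAs and
    5'/3'-shifted isomiRs against hairpin references with embedded mature
    annotations, quantifies them as reads-per-million with between-condition
    ratio tables, computes trimmed-mean-of-M-values (TMM) scaling factors and
    differential-abundance summaries, and provides the common bench-assay
    quantitation formulas (delta-delta-Ct, in vitro processing activity,
    RIP/ChIP enrichment, exponential doubling time). A seeded synthetic-data
    module generates references, negative-binomial read sets with programmed
    5'-offset distributions, and assay measurements with ground truth, so
    every stage of the pipeline is testable without external sequencing data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
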