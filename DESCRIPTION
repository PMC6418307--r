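Package: raslscreen
Title: Analysis of Targeted RASL-Seq Chemical Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for high-throughput targeted transcriptomic (RASL-seq)
    chemical screening of neuronal cultures: plate-design and barcode
    bookkeeping, a negative-binomial screen simulator with known ground
    truth, read-count quality-control filters, spike-in cell-health
    metrics, control-gene log-ratio normalization with Tukey median
    polish, and Pearson-correlation classification of chemicals against
    reference transcriptional signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
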