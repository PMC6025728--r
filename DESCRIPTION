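Package: laminaquant
Title: Layer-Resolved ISH Densitometry and Transcript Diagnostics for
    Developing Retina
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies colorimetric in situ hybridization (ISH) signal in
    laminated retinal sections across postnatal development.  Places
    registered regions of interest in each retinal layer, computes mean gray
    values, references them to the inner plexiform layer, and calls ganglion
    cell layer enrichment and genotype dependency with a two-sample
    Kolmogorov-Smirnov test (exact small-sample enumeration plus the
    asymptotic series).  Aggregates per-age calls into gene-level
    developmental summaries (onset, peak, offset, consistency).  Also
    implements the upstream RNA-seq candidate-selection filter, in-silico
    PCR over transcript isoform models with band-pattern based support
    inference, and riboprobe quality control.  A synthetic-data module
    generates laminated section images, quantification tables and isoform
    panels with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
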