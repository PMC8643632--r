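Package: hadcall
Title: Calling and Characterizing HAT1-Dependent Accessibility Domains from
    Differential ATAC-Seq Peak Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers megabase-scale accessibility domains from a
    differential ATAC-seq peak table by sliding-window smoothing of the
    per-peak log2 fold-change track followed by cutoff-and-gap-merge
    segmentation, and characterizes the resulting domains: size
    distribution, genome fraction, gene density, genomic-feature and
    isochore composition, megabase-binned ChIP peak-density differencing,
    overlap with lamin-associated domains under a circular-rotation
    permutation null, and integration with differential gene expression.
    Includes a fully seeded synthetic-data generator that emulates the
    statistical structure of the real inputs (planted low-accessibility
    domains nested in LAD-like regions) so the whole pipeline is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
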