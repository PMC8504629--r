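Package: smorfkit
Title: Discovery and Classification of Translated Small Open Reading Frames from Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates small open reading frames (smORFs, up to 100 codons)
    from a genome and transcript annotation, classifies them by position within
    their host transcript (canonical, extended, truncated, upstream, downstream,
    overlapping and non-coding classes), calibrates ribosome-profiling P-site
    offsets from a metagene at annotated start codons, scores translation with
    the ORFScore triplet-periodicity statistic, the ribosome release score,
    codon coverage, FPKM and translation efficiency, filters to a non-redundant
    set of actively translated smORFs and writes a genome-browser-compatible
    BED12+ table. Includes a self-contained synthetic-data generator that
    plants smORFs of every class with controllable periodicity and depth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
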