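Package: clonability
Title: Comparison of Bacteria-Clonable and Yeast-Only Clone Libraries of a Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing large-insert genomic clone libraries that
    propagate in bacteria (cosmids, fosmids) with libraries that only
    propagate in yeast (YACs), as in the C. elegans genome project. The
    package derives YAC-exclusive ("gap") segments by interval subtraction,
    profiles repeat content per clone from RepeatMasker output, assesses
    enrichment against matched random-clone resampling nulls, stratifies
    results by chromosome quarter and clone length, and summarizes gene and
    21U piRNA content per library. A synthetic genome/annotation generator
    with a recorded truth file makes every stage testable end to end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
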