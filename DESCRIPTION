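Package: stacktail
Title: Base-Pair-Resolved Structural Variant Detection from Soft-Clipped Read Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects structural-variant breakpoints at base-pair resolution by
    collecting partially aligned (soft-clipped) reads into stacks, pairing
    recurrent clip coordinates into a library of candidate junction sequences,
    realigning the stacked reads to that library, and scoring each candidate
    junction with the support statistic S = sum(Q_i * min(l_A_i, l_B_i)).
    Includes threshold training from labeled scores, collapsing of similar
    calls, windowed call-set comparison, a whole-genome mode driven by external
    breakpoint-pair candidates with coverage-adjusted scores, and a synthetic
    read simulator that plants structural variants and emits truth alignments
    so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
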