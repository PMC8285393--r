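Package: riboterm
Title: Translation Termination Analysis from Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies translation termination from ribosome-profiling
    footprints in transcript coordinates: per-transcript stop-codon pause
    scores, Ribosome ReadThrough Scores (RRTS) over the 3'UTR segment
    between the normal termination codon and the first downstream in-frame
    stop, and stop-aligned metagene profiles. Includes UMI deduplication,
    footprint size selection, P-site offsetting, nonparametric
    condition-vs-condition comparisons (exact and approximate Wilcoxon
    signed-rank and Mann-Whitney U), a generative simulator of terminal
    pausing and stop-codon readthrough for end-to-end validation, and
    plate-screening metrics (percent activation, Z'-factor, hit threshold,
    percent viability, apparent permeability, efflux ratio).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
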