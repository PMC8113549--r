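Package: songkit
Title: Vocal Sequence Statistics and Area X Cell Classification for Songbird
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of annotated zebra finch song and of Area X
    single-nucleus RNA-seq data. Segments syllable annotation logs into song
    bouts, counts consecutive vocal-element repetitions, and scores changes
    between timepoints with the d-prime effect-size statistic; builds syllable
    transition matrices with song-boundary tokens, difference matrices, and a
    template-alignment classifier for syntax alterations (omissions, de novo
    insertions, new transitions). The companion single-nucleus pipeline covers
    UMI/mitochondrial quality filtering, log-normalization, graph-based
    clustering, marker-based cell-type assignment, exclusive dopamine-receptor
    and FoxP2 co-expression classification of medium spiny neurons, pathway
    differential expression, and bootstrapped cluster dendrograms. Two seeded
    generators produce synthetic song logs and synthetic UMI count matrices
    with known ground truth for end-to-end parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    irlba,
    scran,
    ape,
    methods,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    withr
Config/testthat/edition: 3
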