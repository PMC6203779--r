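Package: divtx
Title: Quantifying Transcription Initiation Directionality at Promoters and Enhancers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying and modelling divergent transcription
    initiation directionality from nucleosome-depleted regions (NDRs). Calls
    significant transcription start sites (TSSs) from stranded nascent-RNA
    5'-end counts against an empirical gene-body background, scores core
    promoter sequence with a position-specific first-order Markov model,
    summarises TSS shape with a Shannon-entropy distribution-pattern score,
    segments chromatin into states with a tied-transition multivariate
    Gaussian hidden Markov model over histone-mark signal, relates
    directional features through Spearman partial correlations, and predicts
    forward/reverse initiation ratios with a two-component mixture of linear
    regressions. Includes a synthetic-data generator with planted ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    MASS,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
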