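Package: popadapt
Title: Multi-Level Inference of Local Adaptation from Expression and Sequence Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect local adaptation in structured populations by
    combining transcriptome-wide expression divergence with sequence-level
    population genetics. Implements negative-binomial pairwise contrasts with a
    population-exclusive sign rule for differentially expressed transcripts,
    Bayesian coancestry estimation from marker allele counts under an F model,
    a drift-null posterior-predictive test (H statistic) separating selection
    from shared evolutionary history, per-transcript Tajima's D, Weir-Cockerham
    FST with a simulation-based outlier envelope, inbreeding coefficients,
    variant filtering and LD pruning, Kimura two-parameter divergence for
    triaging inparalogs against putative misassemblies, and an alluvial-ready
    cross-classification of candidate transcripts. A self-contained synthetic
    study generator (F-model drifted markers, negative-binomial counts, a basic
    coalescent with growth and structure, planted paralog pairs) provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    Biostrings,
    vcfR,
    DESeq2,
    optparse,
    withr
Config/testthat/edition: 3
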