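Package: peartools
Title: Amplicon Quantification, pegRNA Design and Enrichment Analysis for
    Prime-Editing Splice Reporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational pipeline for prime-editing experiments read out
    with splice-donor fluorescent reporters (PEAR) and amplicon deep
    sequencing. Provides target geometry and edit application on reference
    amplicons, a seedable synthetic read and cell-population generator, an
    affine-gap semi-global read aligner with anchor filtering and cut-site
    indel calling, per-sample editing/indel/specificity quantification,
    GUIDE-seq dsODN tag counting with mismatch-based off-target filtering,
    pegRNA primer-binding-site and reverse-transcriptase-template design
    with secondary-nick enumeration, and the three-gate enrichment analysis
    with an assumption-driven group-comparison decision tree (ANOVA/Tukey,
    Box-Cox, Kruskal-Wallis/Dunn).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    MASS,
    Rcpp,
    S4Vectors,
    car,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
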