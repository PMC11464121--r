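Package: retroclock
Title: Locus-Specific Retroelement Epigenetic Clocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and application of epigenetic clocks built from
    DNA methylation states of locus-specific retroelements (HERV, LINE, LTR,
    SINE). Annotates methylation-array probes to retroelement loci by
    coordinate intersection, trains penalized linear chronological-age
    predictors (cross-validated elastic net) on retroelement CpG beta values
    or retroelement expression, and provides the downstream analyses such
    clocks are used for: age prediction and evaluation (Pearson r, median
    absolute error), epigenetic age acceleration with group and paired
    contrasts, clock-CpG set intersection, feature-set enrichment by
    Fisher's exact test with FDR control, and test-retest reliability via
    mixed-model intraclass correlation. A synthetic-data module generates
    cohorts with known age signal so every step is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    lme4,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
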