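Package: csrseq
Title: Selection Output Analysis for Compartmentalized Self-Replication
    Directed Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing amplicon deep-sequencing outputs of
    compartmentalized self-replication (CSR) and related directed-evolution
    selections. Reads sequenced pre- and post-selection are genotyped at
    targeted codons against a reference amplicon, per-variant enrichment
    scores (natural-log frequency ratios) are computed and tested with an
    unconditional E-test for two Poisson means, per-variant polymerase error
    spectra (substitutions, indels, frameshifts, transition/transversion
    rates) are profiled, and sequencing-coverage requirements are explored
    by seeded subsampling (detection probability, precision). A
    design-of-experiments module ranks selection factors by importance with
    repeated cross-validated Lasso regression. A seeded simulator of
    saturation-mutagenesis libraries, selection amplification, and noisy
    amplicon reads makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    BiocGenerics,
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    glmnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
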