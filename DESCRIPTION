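Package: tpmdepth
Title: Annotation-Depth Artifacts in TPM-Based Cross-Species Expression Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how transcriptome
    annotation depth distorts transcripts-per-million (TPM) values when gene
    expression is compared directly across species. Provides a block-based
    synthetic transcriptome forge with paralog families and multi-isoform
    genes, an abstract read simulator with multi-mapping compatibility sets,
    an expectation-maximisation read-assignment and TPM quantifier, annotation
    perturbation operations (random subsampling sweeps, paralog removal,
    pre-clinicalization to species-level isoform counts, historical gene-length
    drift), a trimmed-mean-of-M-values (TMM) correction for tpm tables over
    orthologous genes, and the statistical diagnostics that expose the tpm
    denominator-inflation mechanism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    edgeR,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
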