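Package: mirscreen
Title: Whole-Blood miRNA Biomarker Discovery and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for microarray-based microRNA biomarker
    screening in whole blood and its RT-qPCR validation. Provides
    replicate-level summarization and variance-stabilizing (affine-arsinh)
    normalization of intensity data, two-group differential-expression
    screening with Benjamini-Hochberg control and exp-scale fold changes,
    support-vector-machine signature evaluation under repeated stratified
    cross-validation with per-fold t-test filter feature selection and a
    permutation null, and comparative-Ct (2^-ddCt) quantification of qPCR
    data normalized to an endogenous reference. A synthetic cohort generator
    with planted differential features makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
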