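Package: marpipe
Title: Time-Resolved Differential Proteomics of the Microglial Amyloid Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Label-free quantification (LFQ) analysis pipeline for staged
    microglial proteome remodelling in amyloidosis mouse models. Implements
    the consistency filter, per-age-group median normalization, SAM-style
    s0-moderated statistics with permutation-based false discovery rate
    control, temporal onset staging of regulated proteins into early, middle
    and advanced response classes, cross-model intersection into amyloid
    response protein (MARP) tables, proteome-transcriptome concordance
    classification, hypergeometric term enrichment against a custom
    background, and luminescent conjugated oligothiophene (LCO) emission
    spectrum peak-ratio analysis. A synthetic-data generator with planted
    ground truth makes every stage verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
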