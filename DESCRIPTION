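Package: epi2sensa
Title: Analysis Pipeline for RhE-Based Skin Sensitization Assays (Epi2SensA)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data analysis for reconstructed-human-epidermis (RhE) skin
    sensitization assays addressing key event 2 of the adverse outcome
    pathway (keratinocyte activation). Computes LDH-based tissue viability
    against killed-control references, fold induction of four marker genes
    (ATF3, GCLM, DNAJB4, IL-8) from RT-qPCR Ct values with GAPDH
    normalization, applies run and concentration acceptance criteria,
    classifies chemicals as sensitizers or non-sensitizers under the
    validated reference method (VRM) or the modified Epi2SensA criteria,
    and derives interlaboratory validation statistics (within- and
    between-laboratory reproducibility, sensitivity, specificity, accuracy)
    against OECD Performance Standards minima. Includes a synthetic
    assay-plate simulator with known ground truth and the 20-chemical
    reference panel used for similar-method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
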