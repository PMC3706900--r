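Package: osteomir
Title: miRNA and mRNA Outcome Modeling for FFPE Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Survival and chemoresponse modeling for archival (FFPE)
    tumor expression cohorts, built around miRNA profiling of
    osteosarcoma biopsies. Implements supervised principal-components
    recurrence risk prediction with complete cross-validation and
    permutation testing, univariate Cox feature screening, an averaged
    univariate ordinal-logistic-regression ensemble for chemotherapy
    response prediction, miRNA regulatory-activity scoring against
    target gene sets (RE score and random-set GSA), an external-cohort
    signature overlap permutation test, quantile normalization and
    variance filtering, and a synthetic cohort generator that plants
    correlated prognostic blocks, ordinal-response effects and
    miRNA-to-target repression so the whole pipeline is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    limma,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
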