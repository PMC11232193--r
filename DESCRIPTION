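Package: psnet
Title: Patient-Specific ceRNA Networks and Prognostic Triplet Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs competing endogenous RNA (ceRNA) networks of
    lncRNA-miRNA-mRNA triplets that are specific to individual tumor samples.
    A reference network of first-order partial correlations between lncRNAs
    and mRNAs conditioned on a shared miRNA is estimated from normal samples;
    adding one tumor sample at a time yields a perturbed network, and the
    per-sample differential partial correlation defines a patient-specific
    network. Triplets whose differential partial correlations are
    systematically non-zero across a tumor cohort are selected by a Z-test,
    then screened as prognostic biomarkers with median expression
    dichotomization, univariate Cox proportional-hazards models and
    Kaplan-Meier/log-rank analysis. Includes association-list ingestion and
    intersection, a synthetic cohort generator with planted ground truth,
    Cytoscape-compatible SIF/GraphML export, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
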