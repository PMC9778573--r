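Package: reporternet
Title: Network-Integrated Biomarker Discovery from Case/Control Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative biomarker-discovery pipeline for case/control
    transcriptome studies. Performs per-dataset differential expression with
    empirical-Bayes moderated t-statistics and cross-dataset intersection,
    over-representation analysis against user-supplied gene sets, hub-protein
    detection in a DEG-centred protein-protein interaction subnetwork (degree
    and betweenness centrality), reporter transcription-factor and receptor
    scoring by background-corrected Z-score aggregation over regulatory
    networks, pre-clinical diagnostic (ROC/AUC) and prognostic (Cox prognostic
    index, Kaplan-Meier, log-rank, hazard ratio) validation on an independent
    cohort, and cross-validated classification of the resulting gene panel.
    Ships a synthetic-data generator with planted ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    survival,
    jsonlite,
    stats,
    utils,
    class,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    randomForest
Config/testthat/edition: 3
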