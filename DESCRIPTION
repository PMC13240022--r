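Package: regfate
Title: State-Specific Regulon Networks Along Single-Cell Fate Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links terminal single-cell states to state-specific
    transcription-factor regulatory networks. Provides rank-based AUC
    scoring of regulon and differentiation-program activity per cell,
    regulon specificity scores (Jensen-Shannon divergence), connection
    specificity indices with module clustering, k-nearest-neighbour
    integration quality metrics, selection of state-specific high-activity
    regulons, fate-driver-intersected network construction with composite
    CoreScore hub identification, and patient-level signature scoring with
    survival association. Includes a synthetic-data generator with planted
    ground truth so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    survival,
    stats,
    utils,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
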