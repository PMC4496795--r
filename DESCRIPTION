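Package: regrewire
Title: Regulatory Network Rewiring Analysis for Matched Tumor/Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs condition-specific transcription factor (TF) and
    microRNA co-regulatory networks from expression-correlation evidence,
    classifies regulations (unidirectional TF/miRNA, bidirectional TF-TF and
    TF-miRNA feedback loops), quantifies regulation rewiring between normal
    and tumor networks, ranks TF-miRNA feedback loops by differential
    co-expression of standardized Fisher-transformed Spearman correlations
    across cohorts, performs cancer-association and gene-set enrichment with
    Fisher's combined probability, and assembles Connectivity-Map-style
    drug-gene signature subnetworks. Includes a synthetic-data generator with
    planted ground truth so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
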