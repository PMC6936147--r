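Package: dytidriver
Title: Tissue-Weighted Network Prioritization of Cancer Driver Genes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Prioritizes candidate cancer driver genes from a somatic
    mutation cohort by combining three signals: mutated genes are first
    filtered by whether they dysregulate the expression of their network
    neighbors (per-patient z-score outliers), the surviving mutated-gene
    interaction network is weighted by tissue-specific co-expression
    (thresholded absolute Pearson correlation, averaged across tissues),
    and genes are ranked by an edge-clustering-coefficient module score
    multiplied by their variation frequency. Includes top-K
    precision/recall/F-score evaluation against a benchmark gene list, a
    frequency-only baseline, and a synthetic-cohort generator with planted
    driver modules so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, igraph
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
biocViews: SystemsBiology, Network, SomaticMutation, GeneExpression,
    DriverMutation
RoxygenNote: 7.3.3
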