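Package: metastate
Title: Node-Centrality Metastates of Dynamic Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects recurring whole-brain states ("metastates") in
    resting-state fMRI by clustering sliding-window eigenvector-centrality
    patterns of regional BOLD networks. Provides sliding-window Fisher-z
    functional connectivity with framewise-displacement censoring and
    proportional density thresholding, per-window degree and eigenvector
    centrality, two-stage k-means++ clustering under correlation distance
    with elbow-based model selection, dwell-time and transition dynamics,
    a pooled-moment intraclass correlation coefficient for test-retest
    reliability, hub detection, weighted rich-club analysis against
    degree-preserving nulls, and a synthetic-data generator with planted
    ground truth for every pipeline stage. A command-line interface chains
    the stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    cluster
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
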