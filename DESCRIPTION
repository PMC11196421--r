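Package: mazexplore
Title: Exploration Metrics and Age-Group Inference for Virtual Maze Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying free exploration of a virtual maze and
    relating exploration style to wayfinding ability across age groups. The
    maze is represented as a labeled topological graph of decision points
    (target objects and hallway junctions); timestamped key-press logs are
    coded into visit-letter sequences from which ten trajectory measures are
    derived, including Shannon path roaming entropy, clustering of visits and
    the longest hallway sequence. A four-step inference pipeline compares
    groups by sex-adjusted ANCOVA and linear mixed models, tests mediation of
    the age effect on wayfinding success through exploration behavior,
    extracts principal components with permutation-based significance, and
    contrasts logistic age classifiers by DeLong's test for paired ROC
    curves. An agent-based simulator generates synthetic cohorts on the maze
    graph for calibration and testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    car,
    lme4,
    lmerTest,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
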