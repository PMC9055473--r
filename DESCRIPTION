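Package: trajclust
Title: Weight-Loss Trajectory Clustering for Mobile Lifelog Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping 16-week weight-loss trajectories from
    mobile weight-management lifelogs. Simulates or ingests per-user event
    streams (weight, meal, message and step logs), applies an eligibility
    cascade with a flow accounting, standardizes irregular weight series to
    fixed-length z-normalized trajectories, clusters them with k-means under
    dynamic time warping (DTW) using DTW barycenter averaging (DBA)
    centroids and elbow-based model selection, classes weight-change
    outcomes, and compares app-use adherence across clusters cross-
    sectionally and week by week with effect sizes (Cohen's d, eta squared,
    Cramer's V, phi).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
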