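Package: hcnseg
Title: Segmentation of High-Cost High-Need Patient Populations from Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for disaggregating threshold-defined high-cost high-need
    (HCHN) patient populations into clinically distinct subgroups from
    administrative claims. Implements spending-quantile cohort selection,
    diagnosis grouping through a user-supplied multi-level condition
    crosswalk, polar-coordinate encoding of categorical features for
    Euclidean clustering, k-means partitioning with jump-based (partial-F)
    selection of the number of clusters, bootstrap cluster-stability
    assessment with kappa-maximizing label matching and per-cluster Rand
    and Jaccard indices, and deviation-based cluster profiling and
    labeling. A synthetic Medicaid-style claims generator with planted
    cluster structure supports testing and documentation without access
    to proprietary claims.
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
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
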