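Package: pacmir
Title: Pathway Activity Profiling and Cluster-Level miRNA Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Summarizes gene expression into rank-based per-sample pathway
    activity scores, detects differentially regulated pathways between two
    conditions with covariate-adjusted linear models, groups them into
    coordinate clusters on a pathway co-expression network, and prioritizes
    miRNAs that preferentially target each cluster using an inverse-normal
    cluster-targeting statistic with a bootstrap or Gaussian empirical null.
    Includes a synthetic-data generator with plantable signal for every
    pipeline input, comparison baselines (Fisher/Stouffer p-value aggregation
    and per-pathway enrichment hit counts), jackknife stability diagnostics,
    and an end-to-end pipeline driver with a thin command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    limma,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
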