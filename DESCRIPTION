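Package: urbanvar
Title: Meta-Analysis of Urban Effects on Phenotypic Means and Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative meta-analysis of paired urban versus
    non-urban population summaries of avian life-history traits (laying
    date, clutch size, number of fledglings). Computes ratio-based effect
    sizes for means and variation (lnRR, lnCVR, lnVR, SMDH) and arm-level
    log standard deviations from per-arm (mean, SD, n) summaries; fits
    multilevel phylogenetic meta-analytic models by maximum likelihood or
    REML with structured among-study trait variance-covariance matrices;
    pools within-season summaries into among-season means and variances;
    derives phylogenetic correlation matrices from Newick trees with
    Grafen branch lengths; quantifies landscape heterogeneity (Hill
    numbers, q = 1) and urban index within multi-scale buffers on
    categorical land-cover grids; and includes a hierarchical synthetic
    data generator with known truth for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
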