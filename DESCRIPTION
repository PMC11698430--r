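Package: netbackbone
Title: Statistical Backbone Extraction for Weighted Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts network backbones by statistical edge filtering. Implements
    seven hypothesis-testing edge significance filters for undirected, positively
    weighted networks (disparity, Polya urn, marginal likelihood, noise corrected,
    enhanced configuration model, global statistical significance, and locally
    adaptive network sparsification), multiple-testing correction (Bonferroni,
    Benjamini-Hochberg) and backbone extraction at a significance level, together
    with a comparative-evaluation pipeline: p-value similarity, backbone overlap,
    local edge-property correlation, global backbone properties, and
    Kolmogorov-Smirnov distribution ranking. Includes seeded generators for
    heterogeneous synthetic weighted networks with optional planted strong edges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
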