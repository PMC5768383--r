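Package: coexmod
Title: Consensus Co-Expression Modules and Eigengene Network Preservation
    Across Paired Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects consensus gene co-expression modules shared by two
    expression cohorts and quantifies how well the relationships among
    module eigengenes are preserved between them. Provides per-cohort
    Mann-Whitney differential-expression screening, consensus-connectivity
    hub-gene selection, soft-threshold adjacency and topological-overlap
    networks combined into a consensus dissimilarity, average-linkage
    clustering with a fixed-height cut and size-ordered color labels,
    module eigengenes (first principal components) with variance explained,
    eigengene networks, the pairwise eigengene preservation statistic with
    per-module and overall summaries, over-representation analysis of
    user-supplied gene sets with EASE (modified Fisher) p-values, and a
    synthetic paired-cohort generator with planted modules and a tunable
    cross-cohort degradation knob for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
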