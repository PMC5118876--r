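Package: immunesig
Title: De Novo Discovery of Conserved Tumor Immune Gene Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers immune-related gene signatures conserved across multiple
    tumor expression datasets. From normalized feature-by-sample matrices it
    collapses correlated probes to genes, extracts resampling-stable
    co-expression clusters, consensus-clusters candidate immune genes with
    k-means and a self-organizing map, intersects cluster memberships across
    datasets and algorithms into meta-intersections, qualifies candidates by
    hypergeometric immune-term enrichment, scores signature members against a
    leukocyte reference panel of 18 immune cell subsets, collapses signatures
    to per-sample metagenes, and tests metagene-survival associations with Cox
    proportional-hazards models. A synthetic-data module plants known module
    structure, reference-panel markers and survival effects so that the whole
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    survival,
    igraph,
    yaml,
    jsonlite,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
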