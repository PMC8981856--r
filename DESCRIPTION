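Package: phenodist
Title: Ontology-Backed Semantic Distances, Clustering and Archetype
    Visualisation for Mixed Trait Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyse incomplete mixed (qualitative and quantitative) trait
    tables such as germplasm passport and phenotype data. Qualitative
    variables are backed by small ontologies carrying expert pairwise
    distances between modalities, or by offline lookup tables mapping
    modalities to colour coordinates, geographic locations or time periods.
    Per-variable modality distance matrices are normalised and combined into
    a missing-aware weighted semantic distance between individuals,
    alongside a Gower-style dissimilarity for comparison. Downstream steps
    cover principal coordinates analysis, metric multidimensional scaling
    with Kruskal stress-1 diagnostics, Laplacian eigenmaps, six clustering
    algorithms with silhouette and concordance analysis, archetype selection
    per cluster, and decluttered dual-triangle scatterplot-matrix figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    farver,
    generics,
    geosphere,
    ggplot2,
    mclust,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
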