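Package: milletsoil
Title: Soil Quality, Multifunctionality and Microbiome Responses to
    Partial Organic Fertilizer Replacement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for field trials in which a fraction of
    synthetic fertilizer nitrogen is replaced with composted animal manure
    at equal total N-P-K rates. Computes a radar-area soil quality index
    (SQI) from min-max-scored indicators, ecological multifunctionality
    (EMF) as averaged z-scores of soil enzyme activities, and nitrogen-use
    efficiency (partial factor productivity and agronomic efficiency).
    Provides alpha diversity (observed species, Shannon, Chao1),
    Bray-Curtis distances, principal-coordinates ordination and PERMANOVA;
    Spearman co-occurrence networks with FDR-screened edges, topology
    metrics, Louvain modules and Zi-Pi keystone classification; Duncan's
    multiple range test, orthogonal contrasts, Spearman correlation grids,
    and variance partitioning of community composition. A synthetic-data
    generator emulates the 4-treatment x 2-year x 3-replicate trial design
    so every stage is testable without sequence data.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
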