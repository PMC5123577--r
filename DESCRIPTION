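Package: biomebridge
Title: Community Analysis Across a Terrestrial-Freshwater Microbial Gradient
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for OTU-table community ecology along habitat gradients:
    replicate quality control and pooling, abundance filtering, Bray-Curtis
    hierarchical clustering of habitats, habitat generalist/specialist
    classification by occupancy, and Spearman co-occurrence network inference
    with dual rho/p edge thresholds. Includes a synthetic community generator
    that plants generalists, specialists, habitat-block structure and
    correlated OTU pairs so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
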