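Package: nichebox
Title: Climatic-Envelope and Gower-Similarity Species Distribution Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable species distribution modelling pipeline built around
    two classic presence-only models: the BIOCLIM percentile envelope and the
    DOMAIN range-standardised Gower similarity. Provides occurrence cleaning,
    per-cell spatial thinning and train/test splitting; extraction of
    bioclimatic values at points with descriptive statistics, stepwise
    variance-inflation-factor (VIF) variable pruning and principal component
    analysis; grid-wise suitability prediction and six-band classification for
    both models; replicated presence-versus-background AUC validation; and
    current-versus-future climate scenario change accounting (per-class
    geodesic areas, percent change, retained/lost/new habitat transitions and
    patch fragmentation). A synthetic-data module generates spatially smooth,
    cross-correlated climate raster stacks and occurrence samples from a known
    environmental envelope so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
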