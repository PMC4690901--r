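Package: cornernet
Title: Corner Store Food-Supplier Network Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the food and beverage supplier networks
    of urban corner stores. Classifies reported purchases as healthy or
    unhealthy against a promoted-food catalog, builds the healthy (HSN) and
    unhealthy (UHSN) two-mode store-supplier networks, and computes network
    measures: normalized degree centrality, a cumulative-coverage supplier
    core, supplier-category diversity, the shared-supplier one-mode
    projection, and one-mode density. Includes comparison statistics
    (paired and independent t-tests, a node-resampling bootstrap test for
    density differences), bivariate regressions of store characteristics on
    degree centrality with a delivery-exclusion sensitivity re-run,
    great-circle store-supplier distances with nearest-site resolution, a
    synthetic procurement-data generator for end-to-end testing, and a
    packaged supplier roster fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    sandwich,
    testthat (>= 3.0.0),
    tidyr,
    withr,
    xml2,
    yaml
Config/testthat/edition: 3
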