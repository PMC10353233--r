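Package: spatialppp
Title: Spatial Price Indexes for Regional Medical Service Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates spatial price indexes (purchasing power parities)
    for medical services across regions. Matches priced service items
    across regional fee schedules, computes basic-heading parities by the
    Jevons and country-product-dummy (CPD) methods, aggregates them with
    expenditure weights into Laspeyres, Paasche and Fisher bilateral
    indexes, and derives transitive multilateral price-level matrices by
    the GEKS method and by Hill's minimum-spanning-tree method over the
    Paasche-Laspeyres spread. Includes CPI-based back-casting of a
    reference-year comparison to earlier years and a synthetic
    price-system generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
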