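Package: nichediverge
Title: Presence-Only Niche Models and Niche Divergence Tests on Synthetic Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing ecological niche divergence versus conservatism
    between sister species from presence-only data. Implements a maximum-entropy
    habitat suitability model with replicate AUC evaluation and jackknife
    variable contributions, Schoener's D and Hellinger-based I niche overlap on
    sum-to-one suitability surfaces, background-similarity resampling tests
    with buffer- and threshold-based accessible areas, and a multivariate
    (principal-component) niche divergence test comparing actual and background
    niche means. A seeded virtual-species simulator generates spatially
    autocorrelated environmental layers, biotic (tree) suitability layers and
    occurrence records under planted conservatism or divergence, so the whole
    analysis can be exercised and validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
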