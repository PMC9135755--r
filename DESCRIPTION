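Package: allomtrade
Title: Allometric Scaling and Sensory Trade-Off Analysis on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing developmental trade-offs between paired
    anatomical structures (for example visual versus olfactory organs in
    Drosophila) with allometric controls. Implements phylogenetic
    generalized least squares with Pagel's lambda, standardized major axis
    (SMA) line fitting with common-slope and elevation Wald tests and
    pairwise elevation-shift matrices, residual-association and
    conditional-association trade-off tests, trait-ratio bias diagnostics,
    and a synthetic trait simulator (Brownian motion on phylogenies with
    controllable allometric slopes, elevation shifts and residual
    correlations) so that every stage of the pipeline can be validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite
Config/testthat/edition: 3
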