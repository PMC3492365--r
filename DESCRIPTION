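Package: nichecast
Title: Bioclimatic Niche Modelling and Climate-Change Projection for
    Wild Arabica Coffee
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidy pipeline for presence-only ecological niche modelling
    and bioclimatic projection under emission scenarios, built around the
    wild Coffea arabica conservation assessment workflow: cleaning of
    occurrence records with positional-confidence filtering, spatial
    deduplication and thinning; a compact presence-background
    maximum-entropy (MaxEnt-style) model with linear, quadratic, product
    and hinge features fitted by L1-penalised likelihood; locality-quantile
    suitability thresholds (optimal / intermediate / marginal); projection
    onto scenario-by-date climate stacks with a no-migration rule;
    locality and area change accounting; and persistence scoring of
    candidate core localities for in-situ conservation. A synthetic-data
    module generates spatially autocorrelated bioclim-like landscapes,
    scenario deltas and clustered occurrence samples with a known true
    niche, so the whole pipeline is testable without external downloads.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
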