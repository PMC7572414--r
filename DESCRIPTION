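Package: multitroph
Title: Multi-Proxy Trophic Ecology of Small Pelagic Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for combining stomach-content characterization, diet
    DNA-metabarcoding and stable-isotope analysis into a single trophic-ecology
    workflow for small pelagic fish. Provides gut-content metrics (stomach
    filling degree, numerical/biomass/occurrence percentages), OTU-table hygiene
    filters for metabarcoding diet data (global and per-sample frequency
    thresholds, predator removal, low-read sample drop), prey richness,
    Shannon-Wiener diversity, Whittaker beta-diversity and sample-size-based
    rarefaction/extrapolation, Pianka's niche-overlap index with the RA2
    randomization null model, Bayesian standard ellipse areas for isotopic
    niches with directional ellipse overlap, penalized-spline additive models
    with AIC stepwise selection, and a reproducible synthetic-study generator
    with a configurable latitudinal diet gradient for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    MASS
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
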