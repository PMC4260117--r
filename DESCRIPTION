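Package: allocsim
Title: Stand-Level Carbon Allocation and Turnover Schemes Under Elevated CO2
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the partitioning of net primary production among
    foliage, wood, fine roots and reproduction in a forest stand, using the
    four classes of carbon allocation scheme found in ecosystem models:
    fixed (optionally phenology-phased) coefficients, functional-balance and
    pipe-model allometry, resource-limitation priority rules, and canopy
    optimisation. Provides the assumption-centred diagnostics used to
    evaluate such schemes against free-air CO2 enrichment (FACE) experiments
    (allocation coefficients, turnover rates and tissue lifespans,
    whole-canopy specific leaf area, CO2 response ratios, and the NPP
    retention rate), together with a seeded generator of paired
    ambient/elevated FACE-style forcing and observation tables so that the
    full analysis runs at desk scale without site data.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
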