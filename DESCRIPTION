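Package: stresscomm
Title: Multiple-Stressor Effects in Competitive Community Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the joint action of multiple environmental stressors on
    competitive communities. Implements three community models (Lotka-Volterra,
    MacArthur consumer-resource, and Stomp-type phytoplankton light-spectrum
    competition) with a multiplicative trait-level stressor layer, a power
    rescaling that fixes total stressor intensity (TSI) while varying stressor
    richness, closed-form two-species coexistence and biodiversity-effect
    analytics, quasi-Newton equilibrium solving with extinction pruning, and a
    factorial experiment pipeline producing community-level outcome metrics:
    ecosystem-function ratio, species persistence, Bray-Curtis compositional
    resistance, the Loreau-Hector selection/complementarity partition, and the
    stressor coefficient of variation (SCV).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    vegan,
    jsonlite,
    yaml
Config/testthat/edition: 3
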