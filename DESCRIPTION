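Package: foxsna
Title: Social Network Analysis of Red Fox Camera-Trap Detections
Version: 0.1.0
Authors@R: person("Pipeline", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and analyses social networks of urban red foxes (Vulpes
    vulpes) from camera-trap detections at provisioned food patches.
    Detections are collapsed into patch visits, visits into dyadic
    encounters and gambit-of-the-group grouping events, and grouping
    events into simple-ratio-index (SRI) association matrices per
    territory and season.  Global connectivity (density, weighted
    density, transitivity), node centrality (strength, eigenvector,
    Onnela weighted clustering) and discrete assortativity are computed
    per network.  Inference uses restricted data-stream permutations
    (swaps within territory and day), the Manly/Bejder test for
    non-random association, permutation P-values for mixed-model
    coefficients and post hoc contrasts, and intra-class correlation
    repeatability of network position.  A seeded synthetic detection
    stream generator with known ground truth supports end-to-end
    testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
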