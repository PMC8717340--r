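Package: antspread
Title: Spatiotemporal Diffusion Analysis for Gridded Invasive Ant Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for gridded bait-tube surveillance of invasive
    fire ants (Solenopsis invicta). Standardizes positive-tube counts across
    trap densities, interpolates standardized intensity surfaces by ordinary
    kriging, estimates critical dispersal distances from consecutive-year
    cumulative distance curves via an extreme-distance (chord-residual)
    turning-point estimator, builds land-use transition networks scored with
    HITS hub values and Louvain communities, and maps hotspot and diffusion
    areas with a bivariate local Moran's I under conditional permutation
    inference. Includes a seeded synthetic surveillance generator (landscape,
    multi-density tube lattices, yearly spreading process with a known
    dispersal kernel) so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
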