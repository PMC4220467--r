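Package: telemsoc
Title: Telemetry-Based Fission-Fusion Staging and Social Network Analysis for Multilevel Animal Societies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the spatial dynamics of multilevel animal
    societies from simultaneous GPS-collar tracking of their social
    components. Implements the preprocessing chain for collar fixes
    (dilution-of-precision filtering, piecewise cubic-spline gap
    reconstruction, moving-average smoothing), the spatial affinity
    coefficient (SAC) with communication-geometry thresholds for staging the
    timeline into fission, reform, fusion and separation phases,
    nearest-neighbour half-weight-index association networks with
    average-linkage dendrograms cut at maximum weighted modularity, lagged
    and null association rates with decay-model fits, principal coordinates
    embedding, kernel utilization distributions with isopleth home ranges
    and overlap statistics, and a deterministic multi-component trajectory
    simulator with a known fission-fusion schedule for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    MASS,
    pracma,
    minpack.lm,
    ape,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
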