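Package: curvtracks
Title: Quantitative Analysis of Cell Migration on Curved Cylindrical Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying single-cell migration on cylindrical
    (curved) culture substrates. Provides cylinder geometry with principal
    curvature and chord-to-arc unwrapping of projected coordinates,
    curvature-biased persistent random walk simulators with phenotype presets
    (fibroblastic and myofibroblastic keratocytes), synthetic labeled-mask and
    time-lapse generators, blob detection and greedy nearest-neighbour track
    linking, trajectory metrics (per-cell speed, directionality index dx/dy,
    ensemble mean-squared displacement and power-law exponent, 30-degree
    alignment statistics), cell-shape morphometrics (major axis, area,
    eccentricity, solidity), and tie-corrected Kruskal-Wallis and Dunn
    post-hoc tests with Benjamini-Hochberg adjustment, orchestrated by a
    reproducible configuration-driven pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
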