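Package: wormpath
Title: Run-Length Encoding Path Analysis of C. elegans Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies animal search behavior from centroid trajectories.
    A track is resampled on a regular time grid, segmented into steps at
    turning events (heading deviations beyond a threshold angle), and each
    step is described by its length, inter-step angle and speed. Steps are
    symbolized by k-means clustering (sharp versus shallow turns), the
    per-animal symbol strings are compressed by run-length encoding into
    several matrix variants, and eleven run-length descriptors summarize
    the frequency and ordering of movement patterns. Animals are then
    clustered by their descriptor profiles. Includes a two-regime
    (roam/turn) synthetic path simulator so the whole pipeline can be
    exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
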