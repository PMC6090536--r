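Package: timecellmap
Title: Population-Based Topological Map Model of Hippocampal Time Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates interval timing with a population of hippocampal
    "time cells", each modeled as a Gaussian temporal receptive field whose
    width scales with its peak time. An error-driven multiplicative learning
    rule concentrates weight on cells peaking near a to-be-learned criterion
    time, and the weighted sum of the tuning curves (the average time field)
    peaks near that criterion and inherits the scalar property of interval
    timing. Includes multi-criterion training, lesion operators on the
    spatially ordered (ventral-to-dorsal) map, nonparametric half-width
    measurement of time fields, scalar-property diagnostics, and a
    command-line interface for batch simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
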