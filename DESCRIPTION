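Package: flowwalker
Title: Flow-Defined Point-Light Walker Stimuli and Heading-Bias Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates random-dot optic-flow stimuli in which a point-light
    walker's body is defined solely by local differences in the flow field:
    every frame is spatially structureless white noise, and the walker shape
    emerges only from motion. Simulates self-motion over a dotted ground
    plane with a static sky, embeds an articulating 18-joint walker whose
    internal flow can be congruent with the walker, incongruent with it, or
    congruent with the background flow, and supports limited-lifetime dots
    with boundary capture. Also provides the randomized block designs of the
    accompanying heading, facing and articulation experiments, the response
    statistics (pooled heading regression, mirror-collapsed bias summaries,
    repeated-measures ANOVA with Greenhouse-Geisser correction, normal-
    approximation proportion intervals), and a synthetic pooled-flow observer
    that estimates heading from all motion vectors without segmentation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    car,
    optparse
Config/testthat/edition: 3
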