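Package: loomrisk
Title: Locust-Inspired Collision-Risk Estimation from Low-Resolution Frame Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-frame collision risk from grey-scale frame
    sequences using a bio-inspired motion-detection algorithm modelled on
    the looming-sensitive LGMD/DCMD pathway of locusts. Second-order frame
    differencing yields per-element excitation, which is cluster-filtered
    and summed inside a circular "danger zone" to produce a collision-risk
    score; four direction-selective layers with delayed, distance-weighted,
    decaying lateral inhibition provide local motion vectors used to derive
    evasive steering directions and to suppress artifacts from camera shake
    and ground shadows. Includes a deterministic synthetic-stimulus
    generator (looming, translating, camera-shake and ground-shadow
    scenes), per-frame CSV diagnostics, overlay rendering, and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
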