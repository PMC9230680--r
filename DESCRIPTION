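Package: ilizarov
Title: Screw-Theory Force Transmission Analysis for Ilizarov Ring Fixators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing force transmission between a ring external
    fixator and a distracted bone segment during gradual deformity correction.
    Provides screw-theory primitives (twists, wrenches, exponential maps on
    SE(3), product-of-exponentials postures), a fixator model mapping measured
    rod forces and a correction schedule to theoretical bone-end tensions and
    per-period transfer efficiency, CT gray-value to apparent-density to
    elastic-modulus material mapping for compact and cancellous bone, a small
    linear frame surrogate for ring/rod/wire load sharing, and a seeded
    generator of synthetic rod-force and osteotomy-tension time series for
    end-to-end testing without measurement hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
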