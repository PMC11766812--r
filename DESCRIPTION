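Package: magwire
Title: Magnetic-Microwire Microfluidic Immunoassay Modelling and Quantification
Version: 0.1.0
Authors@R: person("magwire", "developers", role = c("aut", "cre"),
    email = "magwire@example.org")
Description: Models the physics and the analysis pipeline of a microfluidic
    immunoassay in which superparamagnetic beads are captured on glass-coated
    soft magnetic microwires magnetized by a permanent-magnet applicator.
    Provides closed-form magnetostatic field landscapes for cuboid magnets and
    transversely magnetized wires, magnetization models for wire and beads,
    overdamped bead-capture and retention simulations in rectangular-duct flow,
    a pump/valve protocol scheduler, flow-cytometry event gating with doublet
    correction and background subtraction, saturation-exponential calibration
    fitting with concentration inversion, quadrature error propagation and
    limit-of-detection logic, and seeded synthetic-data generators for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
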