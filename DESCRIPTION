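Package: fusmap
Title: All-Ultrasound Cranial Mapping and Transcranial Focused
    Ultrasound Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for planning transcranial focused ultrasound (FUS)
    without ionizing imaging. Generates synthetic skull phantoms with
    known ground truth, converts CT-like Hounsfield-unit volumes to
    heterogeneous acoustic property maps, propagates focused beams
    through them with a k-space pseudospectral time-domain solver
    (validated against a Rayleigh-integral oracle for the free-field
    bowl), reconstructs 3D skull maps from pulse-inversion harmonic
    B-mode slice stacks, estimates the FUS incidence angle on the
    skull by plane-fitting the sonicated surface inside the focusing
    cone, and quantifies the relationship between incidence angle and
    transcranial pressure attenuation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
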