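Package: cobaltQA
Title: Automated Daily Treatment-Delivery Verification for a Three-Head
    Cobalt-60 MLC Machine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares a machine delivery log against the approved treatment
    plan for a step-and-shoot IMRT device with three cobalt-60 heads and a
    30-pair multileaf collimator (MLC): patient and prescription identity,
    gantry angles, segment counts, MLC leaf positions, beam-on times with
    source-decay correction, and per-beam integrated primary fluence maps
    with a thresholded pixel pass rate. Emits a single self-contained daily
    verification report (HTML, optionally PDF), and ships a synthetic
    fixture generator with an injectable catalogue of delivery errors for
    testing and commissioning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
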