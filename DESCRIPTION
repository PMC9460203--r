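Package: fmcwvitals
Title: Non-Contact Vital-Sign Extraction from FMCW Radar via Adaptive
    Alpha-Stable EEMD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for recovering respiration and heart rates from
    frequency-modulated continuous-wave (FMCW) radar returns without
    contact sensors. Implements static clutter filtering by slow-time
    mean subtraction, range FFT processing, extended DACM
    (differentiate-and-cross-multiply) phase demodulation, and an
    adaptive ensemble empirical mode decomposition (EEMD) that replaces
    the Gaussian ensemble noise with symmetric alpha-stable noise and
    terminates decomposition early once the respiration mode is
    identified from extrema-rate and amplitude criteria. A full FMCW
    scene simulator (chest displacement, phase signals, complex IF data
    cubes) makes the whole chain testable without radar hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
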