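Package: phonodose
Title: Ambulatory Phonation Monitoring from the Speech Energy Envelope
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Frame-based voice-activity detection for ambulatory voice
    dosimetry. Computes the per-frame energy envelope of a single-channel
    recording, applies an adaptive threshold formed as a weighted sum of the
    current and three preceding frame energies plus a bias, and fits the five
    threshold coefficients with a real-valued genetic algorithm against
    manually labeled speech intervals. Includes a logMMSE (log-spectral
    minimum mean square error) noise-reduction front end, calibrated
    signal-to-noise-ratio noise mixing with four synthetic noise archetypes,
    voice-dosimetry reporting (phonation ratio over time, speech/nonspeech
    segment-duration histograms, frame-level accuracy), a synthetic
    lecture-recording generator with exact ground-truth labels, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
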