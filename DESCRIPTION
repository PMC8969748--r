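Package: hafit
Title: Hearing-Aid Time-Constant Optimization by Contracting Random Search
Version: 0.1.0
Authors@R: person("hafit", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates multichannel wide-dynamic-range-compression hearing-aid
    processing and sensorineural hearing loss (threshold elevation and loudness
    recruitment), and tunes per-channel attack and release time constants with a
    contracting random-search algorithm that maximizes a pluggable
    speech-intelligibility objective. Includes seeded generators for calibrated
    test tones, level steps and speech-surrogate stimuli, audiogram handling
    (cubic completion in log-frequency, pure-tone averages, synthetic sloping
    profiles), an envelope-correlation intelligibility proxy, trace/config file
    I/O and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
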