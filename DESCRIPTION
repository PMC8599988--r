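Package: grftimes
Title: Reconstruct Running Contact and Flight Times from Effective Timings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs ground contact time and flight time of running
    steps from the "effective" timings measured at body-weight crossings
    of the vertical ground reaction force (the quantities that sacral
    inertial sensors deliver). Under a sine-wave model of stance force,
    the time between foot-strike and the first body-weight crossing
    satisfies a transcendental equation; the package solves it
    numerically over a grid of effective timings, characterises the
    feasibility boundary of the model, fits a bivariate polynomial
    surrogate of the solution suitable for real-time use, and provides
    Bland-Altman agreement statistics and a synthetic force-trace
    generator with threshold-based gait event detection for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
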