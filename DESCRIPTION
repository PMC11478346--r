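Package: sprintavp
Title: Sprint Acceleration-Velocity Profiling and Method-Agreement Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates short-sprint kinematic parameters (maximal sprinting speed,
    relative acceleration time constant, maximal acceleration, relative propulsive
    power) from velocity-time traces via a time-corrected mono-exponential model,
    and in situ from velocity-acceleration points harvested from positional
    tracking streams (local or global positioning systems). Includes sprint-trial
    detection in continuous device streams, a method-agreement framework (percent
    bias, percent mean absolute difference, percent residual standard error,
    minimal detectable change at 95% confidence) with bias-corrected and
    accelerated (BCa) bootstrap confidence intervals, and a synthetic study
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
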