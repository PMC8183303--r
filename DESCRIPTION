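Package: pufov
Title: Peripheral Useful Field of View Analysis for Wide-Screen Gaze Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to measure the peripheral useful field of view (pUFOV) from
    wide field-of-view eye-tracking experiments in a three-screen driving
    simulator. Models the simulator screen geometry (pixel to viewing-direction
    conversion, visual angles), generates randomized stimulus grids and
    constrained schedules of color, shape and motion change events, simulates
    synthetic participants with known eccentricity-dependent detection
    profiles, aligns noisy gaze samples to stimulus features with a Markov
    random-walk model, segments the aligned track into saccades, scores
    detection rates, reaction times and saccade amplitudes, and fits Gaussian
    perception-probability profiles over eccentricity with one-way ANOVA
    comparisons between change types.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
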