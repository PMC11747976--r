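Package: motoradapt
Title: Two-State Models of Force-Field Motor Adaptation Under Applied Noise
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis tools for force-field reaching
    experiments with externally applied motor noise. Builds the per-group
    trial schedules (baseline, training, retention and decay blocks with
    error-clamp probes), simulates reaching kinematics and the
    velocity-dependent curl-field forces, generates synthetic cohorts whose
    error-clamp force profiles embody a fast/slow two-state learner plus
    observation noise, computes adaptation coefficients by regressing
    baseline-subtracted force profiles on the ideal compensatory profile,
    fits the multi-rate two-state model by bounded least squares with a
    regularized subject-resampling bootstrap, and fits descriptive logistic
    learning curves and one/two-phase exponential decay curves with AIC
    model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
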