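Package: soniquant
Title: Closed-Loop Cavitation Control and Quantitative Imaging for
    Microbubble-Mediated Blood-Brain-Barrier Disruption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing acoustic-emissions feedback
    control of focused-ultrasound blood-brain-barrier disruption with
    microbubbles. Provides spectral band analysis of passive cavitation
    detector recordings (harmonic, subharmonic and broadband bands with
    noise-floor calibration and event detection), a proportional closed-loop
    acoustic power controller with per-target freeze and safety-reduction
    logic, a synthetic microbubble cavitation plant with bolus kinetics and
    stochastic inertial-cavitation events, R1 relaxometry fitting with
    hemispheric comparison and gadolinium concentration estimation, and
    treatment-outcome statistics (tumor doubling time, Kaplan-Meier survival,
    log-rank tests, geometric summaries, dose conversion).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    survival,
    yaml,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
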