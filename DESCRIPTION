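Package: mbfus
Title: Machine-Learning-Assisted Closed-Loop Control of Microbubble
    Acoustic Emissions
Version: 0.1.0
Authors@R:
    person("mbfus", "maintainers", email = "mbfus@example.org",
           role = c("aut", "cre"))
Description: Tools for studying closed-loop control of microbubble-mediated
    focused-ultrasound (MB-FUS) blood-brain-barrier opening from per-pulse
    passive-cavitation spectra. Provides calibrated harmonic, ultra-harmonic
    and broadband band levels with a 6 dB broadband event rule; a stochastic
    surrogate generator of per-pulse acoustic emissions driven by commanded
    pressure, bolus microbubble kinetics and a latent instability state; a
    small sigmoid multilayer perceptron trained by Levenberg-Marquardt with
    class-balancing under-sampling, confusion metrics and sampling-based
    Shapley attributions; a cross-attention classifier variant with weighted
    cross-entropy and stratified cross-validation; the open-loop, closed-loop
    and ML-assisted closed-loop controller family with microbubble-kinetics
    gating; and experiment-level statistics (event rates, hyper-tangent
    treatment-window fits, skewness, F and Levene variance tests).
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
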