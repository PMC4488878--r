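Package: selfbci
Title: Self-Calibrating Brain-Machine Interface Control from Error-Related Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop simulation and analysis of a self-calibrating
    brain-machine interface for reaching tasks on a discrete grid. The device
    simultaneously infers which goal the user intends and learns the decoder of
    the user's error-related EEG potentials (ErrP), with no supervised
    calibration phase. Goal inference uses a leave-one-out pseudo-likelihood
    over task hypotheses with a heavy-tailed multivariate Student-t predictive
    density (Jeffreys-prior marginalization of per-class Gaussian models),
    signal-power information to break label-symmetric ambiguities, and a
    confidence threshold on pairwise normalized likelihoods. Action selection
    plans over an uncertainty reward by value iteration and switches to greedy
    exploitation once a goal is identified. Includes ErrP feature extraction
    from epoched EEG, a synthetic two-class signal generator for closed-loop
    simulation, supervised (shrinkage-regularized Gaussian) baselines, and
    evaluation machinery: task metrics, moving-average error rate, label
    quality, incremental-calibration curves, and simulated supervised control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    arrow,
    yaml
Config/testthat/edition: 3
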