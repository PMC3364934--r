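Package: cdkclock
Title: Coupled Mammalian Cell-Cycle and Circadian-Clock Dynamics
Version: 0.1.0
Authors@R: person("cdkclock", "maintainers", email = "maintainers@cdkclock.invalid", role = c("aut", "cre"))
Description: Simulation and analysis of the mammalian cell cycle entrained by
    the circadian clock.  Ships a reduced cyclin/Cdk network (a tunable-period
    relaxation oscillator with a bistable Cdk1 switch and growth-factor gating)
    and a reduced circadian oscillator, coupled through circadian transcription
    of Wee1, p21 and cyclin E.  Provides an adaptive ODE engine, entrainment
    and phase-gating analysis, Arnold-tongue scans over autonomous period and
    coupling strength, detection of complex regimes (endoreplication,
    tetraploidy, chaos), scenario presets and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
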