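Package: gpmyocyte
Title: Integrative Guinea Pig Ventricular Myocyte Model with Local-Control
    Calcium Release
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Whole-cell simulation of the guinea pig ventricular myocyte
    coupling electrophysiology, local-control calcium-induced calcium release
    through a 40-state joint L-type channel/ryanodine receptor Markov release
    unit, sarcoplasmic reticulum and cytosolic calcium cycling, mitochondrial
    energetics (calcium-regulated TCA cycle, oxidative phosphorylation,
    uniporter and exchangers), and isometric crossbridge force. Ships the
    stimulation and clamp protocols used to characterise the model (pacing,
    voltage-step families, action-potential clamp, S1-S2 restitution,
    frequency staircase, workload transitions, uniporter block) and the
    analysis metrics derived from them (action potential duration, transient
    timing, excitation-contraction coupling gain, integrated flux fractions,
    fractional release, restitution time constants).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    stats,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    minpack.lm,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
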