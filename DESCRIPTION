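Package: cardiodecon
Title: Closed-Loop 0D-1D Multiscale Hemodynamics and Microgravity
    Cardiovascular Deconditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A closed-loop multiscale model of the human circulation coupling a
    one-dimensional description of the large arteries (mass and momentum balance
    with a nonlinear viscoelastic tapered tube law) to lumped RLC compartments
    for the microcirculation, venous return, pulmonary circulation and the four
    contractile heart chambers (time-varying elastance with atrial kick,
    dynamic valve opening), under short-term arterial baroreflex control.
    Includes a configurator that transforms the supine one-g baseline into the
    long-term weightlessness (zero-g) adaptation point via regional blood
    shift, total blood volume reduction, cardiac and vascular parameter
    changes, and baroreflex re-baselining; an analysis layer computing cardiac
    indexes (stroke volume, ejection fraction, cardiac output, stroke work,
    tension-time index, rate-pressure product, central venous and arterial
    pressures, augmentation index) and the normalized signal difference (NSD)
    waveform-similarity metric; and a regression harness comparing paired runs
    against published hemodynamic variation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
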