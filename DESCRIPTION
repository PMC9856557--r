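Package: lipusdlvo
Title: Ultrasound-Triggered Gold-Nanoparticle Drug Release Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coupled multiphysics model of low-intensity pulsed ultrasound
    (LIPUS) triggered doxorubicin release from gold-nanoparticle (GNP)
    carriers. An axisymmetric Helmholtz solver with perfectly matched
    layers computes the acoustic pressure field of a baffled piston
    transducer; the absorbed power density drives a transient Pennes
    bioheat solve of the ex vivo tissue and GNP chamber; the resulting
    chamber temperature feeds a DLVO colloid-stability model (van der
    Waals plus linear-superposition electrostatics) that extracts the
    energy barrier to nanoparticle aggregation and predicts drug release
    against a calibrated barrier threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
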