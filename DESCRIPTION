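Package: nocimech
Title: Contact Mechanics and Receptive-Field Modelling for Larval
    Nociceptors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Biophysical toolkit for studying how Drosophila larval class
    IV dendritic arborization (c4da) nociceptors sense localized poking.
    Implements Hertzian sphere-on-surface contact mechanics together with
    the calibration arithmetic of a piezo/strain-gauge poking device; an
    axisymmetric linear-elastic finite-element contact solver for a rigid
    sphere indenting a layered cuticle-on-PDMS composite, returning
    surface maps of perpendicular pressure and lateral tension; SWC
    morphology input/output with modified Sholl analysis,
    distance-to-dendrite maps and stimulus-position sampling; a
    calibrated stochastic generator of dense planar dendritic arbors and
    of Boltzmann-shaped force-response data; Monte-Carlo estimation of
    dendritic activation probability under pressure-only, tension-only
    and combined sensitivity scenarios; and Boltzmann dose-response
    fitting with half- and full-activation force estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Matrix,
    graphics,
    grDevices,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
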