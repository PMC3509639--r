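Package: kappa2sim
Title: Monte-Carlo Estimation of the FRET Orientation Factor in Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Numerical estimation of the distribution and average of the
    Forster resonance energy transfer (FRET) orientation factor kappa-squared
    for donor and acceptor fluorophores confined to parallel planes, as in
    lipid bilayer leaflets.  Dipole orientations are sampled from truncated
    Gaussian distributions of the tilt cosine with uniform azimuths, and
    kappa-squared is averaged either uniformly or with inverse-sixth-power
    distance weights over one or two acceptor planes with exclusion distances.
    Closed-form references (isotropic kappa-squared density, Knoester-van
    Himbergen average for identically oriented planar dipoles) support
    validation, and planar energy-transfer decay laws with incomplete-gamma
    kinetics translate average kappa-squared into FRET efficiency curves.
    A catalogue of common membrane probe pairs is bundled, together with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
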