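Package: resp2kit
Title: Two-Stage Restrained ESP Charge Fitting with Gas/Aqueous Mixing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives fixed partial atomic charges for small organic
    molecules by restrained electrostatic-potential (RESP) fitting on
    Merz-Singh-Kollman shell grids, using the two-stage protocol with
    chemical-symmetry constraints, and combines separately fitted
    gas-phase and aqueous-phase charge sets through a polarity mixing
    parameter delta. Includes a synthetic point-charge ESP generator so
    the whole fitting pipeline can be exercised and validated without a
    quantum-chemistry engine, plus evaluation machinery for non-bonded
    force-field models: Lennard-Jones typing over five atom types, a
    Tikhonov-regularized property objective, liquid-property estimators
    (density, heat of vaporization, dielectric constant from box-dipole
    fluctuations), error metrics, and a derivative-free optimizer with
    step-size and objective-change stopping rules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
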