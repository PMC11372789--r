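Package: screwfe
Title: Compression-Screw Pretension Modeling Methods for Implant Finite-Element Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Compares finite-element modeling methods for pretensioned
    compression screws that fix an implant plate to bone. Implements the
    empirical chain from CT intensity to bone apparent density, elastic
    modulus, shear strength, screw pullout threshold, stripping and
    insertion torques, and inferred per-screw pretension forces; a small
    linear-elastic tetrahedral finite-element engine with tied and
    frictionless-contact interfaces, grounded boundary springs, bolt-load
    pretension sections, pseudo-thermal contraction loads and
    equal-and-opposite force pairs; six screw modeling methods (TIE,
    BL-CF, BL-CL, ISO, ORT, FOR) run as two-step pretension/simulation
    analyses; Secant-method calibration of the physics-based methods;
    and post-processing of axial force profiles, peak von Mises stress
    and pullout/fatigue failure likelihood. A synthetic assembly
    generator produces conforming screw-implant-bone meshes at desk
    scale so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
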