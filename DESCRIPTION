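Package: membelast
Title: Membrane Elasticity from Area Fluctuations of Simulated Lipid Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of NPT molecular-dynamics output for lipid
    bilayer mechanics. Estimates the area expansion modulus K_A from
    equilibrium fluctuations of the projected membrane area of a tensionless
    bilayer, measures bilayer thickness as the peak-to-peak distance of the
    phosphorus number-density profile along the membrane normal, and combines
    the two into the bending rigidity via the polymer-brush relation
    kappa = K_A (d - d0)^2 / 24. Statistical errors are obtained by block
    averaging of the correlated time series. A synthetic-ensemble generator
    with known ground-truth parameters makes every stage testable without
    running molecular dynamics. Readers are provided for xvg-style, CSV/TSV,
    GRO and PDB inputs, plus a TOML-configured command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
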