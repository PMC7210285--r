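Package: volsource
Title: Volumetric Source Function Analysis of van der Waals Interaction Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Decomposes the electron density inside van der Waals interaction
    volumes into per-atom contributions. Non-covalent interaction regions are
    located with the reduced density gradient and classified by the sign of the
    middle Hessian eigenvalue; the grid is partitioned into atomic basins with
    the Yu-Trinkle fractional-weight scheme; and the source function is
    integrated over the interaction volume by Monte Carlo sampling to give each
    atom's electron contribution (the volumetric source function), together
    with the Gatti reliability parameter of the reconstruction. Reads and
    writes Gaussian cube files and XYZ geometries, and ships analytic Gaussian
    and promolecular model densities with closed-form derivatives for
    validation and synthetic fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
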