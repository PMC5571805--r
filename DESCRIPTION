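Package: rcross
Title: Cross-Validation Diagnostics for Multipole Charge-Density Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects overfitting in aspherical-atom (Hansen-Coppens multipole)
    crystallographic refinement by k-fold cross-validation. Refines a multipole
    model against k training sets plus the full data set, computes the pooled
    R_cross statistic and resolution-shell Delta-R values per strategy step,
    and runs parameter-distribution (Shapiro-Wilk, Cochran-corrected),
    error-map and QTAIM bond-critical-point diagnostics. Includes a structure
    factor engine with third-order Gram-Charlier anharmonic displacement,
    SHELX HKLF4 reflection I/O, Gaussian cube output, and a synthetic-fixture
    generator of toy crystals with known ground truth for testing the
    methodology end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'cell.R'
    'spacegroup.R'
    'harmonics.R'
    'radial.R'
    'model.R'
    'constraints.R'
    'reflections.R'
    'scattering.R'
    'topology.R'
    'refine.R'
    'crossval.R'
    'diagnostics.R'
    'synthfix.R'
    'plots.R'
    'rcross-package.R'
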