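Package: spiractin
Title: Coarse-Grained Actin Filament Mechanics and Superhelix Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how mechanical force reshapes filamentous
    actin. Builds the canonical F-actin helical lattice as a bead-spring
    network, evaluates its harmonic bond/angle/dihedral energetics, and
    integrates Langevin dynamics under tension and compression protocols.
    Calibrates spring constants against stretch-stiffness and twist-variance
    targets, measures instantaneous helical rise and twist along deformed
    variable-radius filament axes, quantifies superhelical (oscillatory)
    character of 3D filament traces via PCA (wavelength, amplitude, phase
    offset, cross-section ellipticity, ice-plane orientation), models
    thermal curvature distributions with a worm-like-chain Boltzmann form,
    picks superhelical filament segments from 2D segmentation maps by a
    dual-sign curvature criterion with per-filament non-maximum suppression,
    and quantifies per-subdomain C-alpha displacements between protomer
    models. Synthetic-data generators with machine-readable ground truth
    make every analysis stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    bio3d,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
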