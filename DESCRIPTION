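Package: untangler
Title: Escaping Density-Misfit Barrier Traps in Multi-Conformer Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for diagnosing and escaping density-misfit barrier traps
    in two-conformer (altloc) macromolecular models. Implements a weighted
    statistical-geometry model-quality score (wE) that combines chi-square
    weighted mean energies, worst-outlier weights, a clipped energy plateau
    and mean Lennard-Jones nonbond energy; a real-space density-versus-
    geometry toy refiner over Gaussian-atom density; and four trap-escape
    maneuvers (weight snap, rectified simulated annealing, swap-and-rerefine,
    and the pincer maneuver), together with a synthetic fixture generator
    that builds tangled two-conformer bead-peptide ensembles with a known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'untangler-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'restraintLibrary.R'
    'modelIO.R'
    'restraints.R'
    'weScore.R'
    'density.R'
    'refine.R'
    'untangle.R'
    'synthetic.R'
    'cli.R'
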