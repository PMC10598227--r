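Package: noetools
Title: NOE Distance Restraints, Restrained Refinement and NMR Ensemble
    Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for solution-NMR structure determination of protein-ligand
    complexes: parsing, classification and accounting of NOE distance,
    hydrogen-bond and TALOS-derived dihedral restraints; effective distances
    for ambiguous (pseudoatom) restraints under both r^-6 averaging and r^-6
    summation; a flat-bottom restraint potential with analytic gradients and a
    Cartesian restrained refiner with seeded perturb-and-minimize pools and
    lowest-energy selection; an R/S enantiomer screen based on chirality
    impropers and NOE energies; ensemble validation (violation reports under
    both averaging conventions, average pairwise region RMSD, ligand contact
    sites); and a synthetic alpha-helix plus chiral toy-ligand fixture
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
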