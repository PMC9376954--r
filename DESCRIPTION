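Package: fibrilsim
Title: Coarse-Grained Two-Bead Peptide Aggregation: Simulator, Order
    Parameters, and Aggregation-Fragmentation Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for studying peptide fibrillation with a
    minimal implicit-solvent bead model that represents each residue by a
    backbone and a side-chain superatom, plus modified terminal caps. Provides
    the MARTINI-style force field (harmonic bonds, cosine-harmonic angles,
    Lennard-Jones and repulsive-only terminal interactions) with analytic
    forces, a stochastic leapfrog (Langevin) integrator and steepest-descent
    minimizer, cutoff-based single-linkage cluster analysis under periodic
    boundary conditions, the end-to-end and backbone-backbone orientational
    order parameters used to classify aggregate morphology (amorphous,
    amyloid-glass, multi-ribbon/annular, single-ribbon fibril), and a
    three-parameter reversible Smoluchowski coagulation-fragmentation rate
    model with its exact Gillespie stochastic counterpart, a small-system
    master-equation solver, and a global least-squares fitter for the kinetic
    observables (monomers, dimers, trimers, total cluster count). GRO and XYZ
    coordinate input/output and programmatic fixture generators are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
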