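Package: qmmd
Title: Desk-Scale QM/MM Molecular Dynamics with a Gaussian-Basis
    Multireference Quantum Core
Version: 0.1.0
Authors@R:
    person("qmmd", "developers", email = "qmmd@example.org", role = c("aut", "cre"))
Description: A compact hybrid quantum-mechanics/molecular-mechanics (QM/MM)
    molecular dynamics engine for small solvated chromophore models.
    Provides contracted Cartesian Gaussian integrals up to d functions,
    restricted Hartree-Fock with DIIS and direct-SCF Fock builds under
    point-charge electrostatic embedding, MP2, CIS, determinant-based
    CASCI with direct-CI sigma builds (Davidson and LOBPCG eigensolvers),
    two-step state-averaged CASSCF, an AMBER-functional-form molecular
    mechanics engine with TIP3P water and a spherical droplet restraint,
    link-atom QM/MM boundary treatment with charge redistribution,
    velocity-Verlet ground- and excited-state dynamics with emission-energy
    analysis, and Amdahl/Karp-Flatt parallel-efficiency metrics for timing
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    graphics,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
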