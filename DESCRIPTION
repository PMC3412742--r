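Package: anmpbsa
Title: Side-Chain Anisotropic Network Models and MM/PBSA Bookkeeping for
    Protein-Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to judge the feasibility of multi-stoichiometry
    ligand-receptor complexes such as lymphotoxin bound by one, two or three
    TNFR1 chains. Implements a side-chain-augmented anisotropic elastic
    network model with distance-shell, disulfide and secondary-structure
    force constants; normal-mode fluctuation, overlap and correlation
    analyses; trajectory observables (Kabsch RMSD, RMSF, dynamic
    cross-correlation, geometric hydrogen bonds, Shrake-Rupley solvent
    accessible surface and buried interface area, distance monitors); and an
    MM/PBSA free-energy ledger with gas-phase Coulomb and Lennard-Jones
    sums, a linear-SASA apolar solvation model, imported Poisson-Boltzmann
    polar terms, and single- versus separate-trajectory assembly with
    fractional stoichiometry. Synthetic-data generators provide toy
    structures, network-consistent Gaussian ensembles, planted
    hydrogen-bond interfaces and energy tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
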