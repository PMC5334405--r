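Package: rpcdock
Title: FFT Rigid-Body RNA-Protein Docking with RMSD-Based Knowledge Rescoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigid-body docking of an RNA ligand onto a protein receptor by
    FFT-accelerated translation scans over a lattice of Euler rotations,
    scoring geometric complementarity plus distance-dependent-dielectric
    Coulomb electrostatics on 3-D grids. Docked poses are rescored by a
    knowledge-based residue-base pair potential in which native pairs are
    clustered by RMSD and cluster energies follow inverse-Boltzmann counts.
    Includes CAPRI-style decoy assessment (receptor, ligand and interface
    RMSD, native and non-native contact fractions) with sequence-alignment
    residue mapping, readers and writers for the G_DATA pose format and
    dotted key-value parameter files, a command-line front end, and a
    deterministic synthetic protein/RNA fixture generator with known native
    poses for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
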