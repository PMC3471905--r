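Package: enactin
Title: Elastic-Network Mechanics of G-Actin with Breakable Links and
    Coarse-Grained Ligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear overdamped dynamics of anisotropic elastic-network
    (ANM) models of proteins, developed around the intramolecular mechanics
    of the actin monomer. Builds Calpha bead-spring networks from PDB
    coordinates, selects the cutoff by the six-zero-eigenvalue criterion,
    augments the harmonic network with breakable truncated Lennard-Jones
    links derived from a second (filament-like) conformation, and models
    nucleotides phenomenologically (ADP as one elastically attached node,
    ATP as an ADP-phosphate dimer with pre-strained links). Provides
    perturbation-response protocols (global and single-residue force
    ensembles with rigid-body immobilization), normal-mode analysis,
    domain order parameters (inter-subdomain distances and the dihedral
    twist angle), Langevin thermal sampling, and a synthetic two-domain
    generator so the full pipeline runs without any structure download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    bio3d,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
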