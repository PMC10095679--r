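Package: gamdkit
Title: Gaussian-Accelerated Dynamics and Trajectory Analysis on Toy Systems
Version: 0.1.0
Authors@R: person("gamdkit", "developers", email = "gamdkit@example.org",
    role = c("aut", "cre"))
Description: Desk-scale implementation of Gaussian-accelerated molecular
    dynamics (GaMD) with a harmonic boost potential, free-energy reweighting
    by exponential average and second-order cumulant expansion, free-energy
    landscapes with basin detection, principal component analysis of
    collective motions, dynamic cross-correlation maps, structural
    fluctuation metrics (RMSD, RMSF, delta-RMSF, radius of gyration) and
    geometric interaction-network analysis (hydrogen bonds with occupancy,
    salt bridges, ring-centroid and group-centroid distances, ion
    coordination). Ships analytic toy potentials, a Langevin (BAOAB)
    sampler, synthetic trajectory generators with known ground truth, and
    multi-model PDB / XYZ trajectory input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
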