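Package: dimerMSM
Title: Markov State Models of Reversible Protein Dimerization Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and validates Markov state models (MSMs) of reversible
    protein-protein association from multi-replica coordinate trajectories of
    a two-chain, two-domain system such as the betaB2-crystallin homodimer.
    Features trajectories as inter-monomer domain centre-of-mass distances,
    reduces dimensionality with time-lagged independent component analysis
    (TICA), discretizes into microstates with k-means, estimates a reversible
    maximum-likelihood transition matrix, validates it with implied timescales
    and the Chapman-Kolmogorov test, coarse-grains into metastable macrostates
    with PCCA++, and computes stationary free energies, committors, reactive
    fluxes and mean first passage times between macrostates. Includes
    structural observables (binding/unbinding event detection with hysteresis,
    distance population fractions, inter-chain residue contact maps, Kabsch
    RMSD), a config-driven end-to-end pipeline, and synthetic trajectory
    generators (exact Markov-jump chains with distance emissions; a Brownian
    toy dimerization of two rigid bodies) with known ground-truth kinetics
    for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    data.table,
    igraph,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
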