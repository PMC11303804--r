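Package: euclidff
Title: Euclidean-Attention Equivariant Machine-Learned Force Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An equivariant transformer interatomic potential built on
    per-atom spherical-tensor representations ("Euclidean variables") whose
    rotational information enters attention weights only through cheap
    per-degree invariant contractions, avoiding full SO(3) tensor-product
    convolutions. Provides the real spherical-harmonic and Clebsch-Gordan
    machinery, the attention/interaction transformer blocks with analytic
    forces, energy-and-force training, molecular-dynamics engines (velocity
    Verlet, Langevin, Nose-Hoover), MD stability diagnostics, trajectory
    observables (radial distribution functions, velocity-autocorrelation
    power spectra, radius of gyration, dihedrals, harmonic normal modes and
    zero-point energy), and minima-hopping exploration of potential energy
    surfaces with disconnectivity graphs. Analytic toy potentials
    (Lennard-Jones clusters, harmonic and double-well molecules) supply
    fully labeled synthetic datasets so every stage can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
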