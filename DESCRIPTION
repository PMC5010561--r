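Package: excitonxs
Title: Frenkel-Exciton Simulation of Metal L-Edge X-Ray Spectra of Molecular Dimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates metal L-edge X-ray absorption (XAS), resonant inelastic
    X-ray scattering (RIXS), and partial fluorescence yield (PFY) spectra of
    van der Waals dimers from monomer electronic-structure data using a
    Frenkel-exciton model. Aggregate states are built as direct products of
    spin-orbit coupled monomer eigenstates in one- or two-particle exciton
    bases, coupled through point transition-dipole Coulomb terms, with
    configurable coupling-neglect rules, core-state energy windowing,
    energy-dependent lifetime broadening, Gaussian pulse broadening, Boltzmann
    initial-state weighting, and numerical orientational averaging for freely
    tumbling molecules. Includes a seeded synthetic-monomer generator emulating
    the manifold structure of an iron porphyrin (hemin-like) complex, so the
    full pipeline is testable without external quantum-chemistry output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
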