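Package: fretkappa
Title: FRET Orientation Factors from Transition-Charge Electronic Couplings
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of the Förster resonance energy transfer (FRET)
    orientation factor for dye-protein conjugates. Computes electronic
    couplings between chromophores in the dipole-dipole approximation and
    from atomic transition charges (TrESP), extracts an effective
    orientation factor from the transition-charge coupling, inverts the
    Förster equation to infer donor-acceptor distances from measured rate
    constants, tabulates the sensitivity of the inferred distance to the
    spectral overlap and refractive index, aggregates per-snapshot
    statistics over trajectory ensembles, and searches donor orientations
    on an Euler-angle grid with steric clash filtering against the
    surrounding protein. Includes seeded generators for synthetic
    chromophores, restricted-wobble trajectories and partial protein
    shells with analytically known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
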