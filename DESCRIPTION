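Package: hingekit
Title: Two-State Hinge Protein Backbone Generation and Conformational-Selection Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing two-state "hinge" proteins built
    from helical repeat scaffolds. Generates a second backbone conformation by
    shifted re-alignment of a copy of the parent protein along a pivot helix,
    assembles the effector-free (state X), effector-bound (state Y) and
    state-Y-complex models, gates candidate designs with a two-state contact
    energy criterion, and selects spectroscopic label sites and disulfide staple
    sites. Implements the coupled three-state kinetic model (X, Y, Y+peptide)
    linking the hinge conformational pre-equilibrium to effector binding,
    simulators for FRET/FP/DEER-style observables, and the corresponding fitting
    routines: single-exponential association fits, pseudo-first-order slope
    regression, tight-binding titration isotherms, distance-distribution mixture
    decomposition, and inference of the state-Y fraction from on-rate ratios.
    Includes a deterministic generator of ideal helical-repeat backbones so the
    full pipeline is testable without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
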