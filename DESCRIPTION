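Package: lmdk
Title: Low-Mass Molecular Dynamics Sampling Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for studying configurational sampling
    enhancement by uniform atomic-mass reduction in classical molecular
    dynamics.  Provides a minimal constrained MD engine (velocity Verlet,
    SHAKE/RATTLE bond constraints, Berendsen thermostat) for toy systems,
    executable mass-scaling/time-step-scaling conversions with exact
    trajectory-equivalence verification, unweighted Calpha/Cbeta RMSD
    superposition and native-state classification, and a folding-kinetics
    pipeline: native-state population statistics, first-passage folding
    records, Kaplan-Meier and exponential survival estimation of folding
    times, two-state kinetics diagnostics, and population-curve comparisons.
    Includes a two-state Markov folding simulator, a double-well bead-chain
    folder, and transcribed benchmark folding statistics for the
    beta-hairpins CLN025 and chignolin.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    survival,
    bio3d,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
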