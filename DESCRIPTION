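Package: isnet
Title: Inhibition-Stabilized Attractor Networks as Finite-State Machines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of networks of coupled bistable
    excitatory-inhibitory rate-unit pairs in the inhibition-stabilized regime.
    Provides a clamped threshold-linear rate-model integrator, closed-form
    fixed-point and stability analysis of a single pair, an inverse solver for
    pair weights from a target Jacobian trace and determinant, constrained
    random network construction under Dale's law, attractor-state enumeration,
    stimulus-evoked transition graphs with itinerancy scoring, finite-state
    machine extraction by breadth-first simulation, and scoring of the
    extracted machines on a six-cue two-alternative evidence-accumulation
    task (reliability, psychometric curves, primacy and recency).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
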