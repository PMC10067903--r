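Package: hergblock
Title: State-Dependent Versus Conductance-Scaling Models of hERG Channel Block
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing two ways of modelling drug block of the hERG
    potassium channel (IKr) in cardiac safety simulation: a nine-state Markov
    model with explicit drug-bound states capturing state-dependent binding and
    trapping (the SD model), and a six-state model whose maximal conductance is
    scaled by a Hill-curve-derived unblocked fraction (the CS model). Includes
    voltage-clamp simulation under Milnes-style and state-selective protocols,
    Hill/IC50 calibration of the conductance-scaling model against the
    state-dependent model, embedding of either hERG variant in a human
    ventricular action-potential model to compute APD90, qNet and
    early-afterdepolarisation flags, per-concentration comparison metrics
    (RMSD, mean difference, signed RMSD), and a virtual-drug sensitivity sweep
    mapping where the two model classes are interchangeable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
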