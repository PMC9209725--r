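Package: neurocycle
Title: Dynamical Models of Cell-Cycle Re-Entry in Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ordinary differential equation models of the control circuits
    that drive aberrant cell-cycle re-entry in postmitotic neurons, together
    with the numerical machinery needed to analyse them: stiff integration,
    multistart equilibrium enumeration, stability analysis, one- and
    two-parameter bifurcation sweeps with saddle-node and cusp localization,
    knockout/inhibitor perturbation scenarios, and parameter sensitivity via
    threshold fold change. Three calibrated model modules are shipped: an
    amyloid-beta driven bistable ERK switch built on the competition between
    cyclin D and p35 for Cdk5; a calcium/ROS redox switch built on APC/C-Cdh1
    inactivation with glutaminase and cyclin B feedback loops; and a DNA
    damage module with separated thresholds for cell-cycle re-entry and
    p53-dependent apoptosis. A companion transcriptome toolkit computes
    gene-set eigengenes, their trait correlations with Student asymptotic
    p values, and synthetic expression matrices with planted co-expression
    modules for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
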