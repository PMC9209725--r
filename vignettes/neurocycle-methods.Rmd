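---
title: "Models and methods: cell-cycle re-entry switches in neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: cell-cycle re-entry switches in neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(neurocycle)
```

## The scientific problem

Differentiated neurons are postmitotic: high levels of cyclin-dependent
kinase inhibitors (p21, p27), hypophosphorylated retinoblastoma protein
(Rb) and active APC/C-Cdh1 keep the cell-cycle machinery off. In
neurodegeneration this barrier fails — neurons re-express cell-cycle
activators, re-enter the cycle, and die. `neurocycle` implements three ODE
modules for the main routes to re-entry, each built around positive
feedback loops that turn a graded insult into a switch:

1. **ERK switch (module 1).** Amyloid-beta drives nuclear export of p27.
   Cytosolic p27 stabilizes the CycD–Cdk5 complex, so cyclin D competes p35
   away from Cdk5. Free cytosolic p35–Cdk5 is the repressor of MEK; when it
   falls, ERK fires, and active ERK drives further CycD synthesis. The loop
   `ERK -> CycD -> Cdk5 sequestration -> less MEK repression -> ERK` makes
   the response bistable: activation (SN1) and deactivation (SN2) occur at
   different amyloid-beta levels, both positive — the switch is reversible
   if the stimulus is removed completely.

2. **Redox switch (module 2).** Amyloid-beta or glutamate raise
   intracellular calcium; calpain (cooperativity 2) cleaves p35 into the
   longer-lived p25, and p25–Cdk5 phosphorylates (inactivates) both Rb and
   APC/C-Cdh1. Two feedback loops close through Cdh1: mutual antagonism
   with CycB–Cdk1, and `Cdh1 -| Gls1 -> glutamate -> Ca -> p25 -| Cdh1`.
   Active Cdh1 also supports NADPH (a direct stand-in for the
   Pfkfb3/pentose-phosphate/glutathione route), so Cdh1 loss both raises
   ROS production (CycB, calcium) and lowers scavenging. With both loops
   intact the high-ROS state persists at zero amyloid-beta: the transition
   is irreversible. Knocking out either loop alone restores a deactivation
   fold at positive input.

3. **DNA-damage switch (module 3).** Damage boosts CycD synthesis,
   stabilizes E2F, and (via p53 helper) induces p21. At low damage the CDKI
   barrier exceeds total cyclin activity and the cell stays arrested. Past
   a first threshold, cyclins overcome p21, Rb is phosphorylated in two
   steps (CycD–Cdk4/6 then E2F-induced CycE–Cdk2), and the
   `E2F -> CycE -> Rb hyperphosphorylation -> free E2F` loop locks in:
   re-entry is irreversible. A second, higher threshold converts p53 from
   helper to killer through the p53DINP1 positive feedback — a separate
   bistable switch whose two folds both sit at positive damage. The window
   between the two thresholds is the repair state: re-entry with p53 still
   in helper form and a high p21 level.

All state variables are dimensionless relative concentrations; rate
constants have units of inverse time (arbitrary units, "a.u."). The time
axis is not calibrated to disease progression — only the order and
qualitative shape of events is meaningful.

## Kinetic conventions

Mass action is the default for synthesis, degradation, association,
dissociation and transport. Protein interconversion cycles (ERK
activation, Rb and Cdh1 phosphorylation) are Michaelis–Menten with small
Michaelis constants, which makes them zero-order ultrasensitive — the
ingredient that sharpens the feedback loops into genuine saddle-node
bifurcations. Cooperative activation steps (calpain by calcium, E2F
autoactivation, E2F-driven CycB, p53DINP1 induction, helper-to-killer
conversion) are Hill functions. Complex formation is fast relative to the
synthesis/degradation/transport scale (association rates at least ten times
the slow scale), so the p27/p35/Cdk5 totals in module 1 are honest
conserved quantities of the ODE system rather than algebraic constraints.

Knockouts follow a uniform convention: the synthesis or activation rate of
a dynamic species is set to zero; for a species modelled as a fixed total,
the total is set to zero. The input (amyloid-beta or DNA damage) enters as
a constant dimensionless level, optionally stepped at a stated time.

Two structural choices deserve mention because the mechanistic accounts in
the literature are compressed at these points and we had to commit to one
mechanism:

* In module 1 the MEK repressor is the *free cytosolic* p35–Cdk5 dimer;
  the p27-bound trimer is inactive toward MEK. This is what lets a CycD
  knockout still reach the high-ERK state (cytosolic trimer formation
  removes the repressor) unless the direct amyloid-beta trimer-dissociation
  term (`k_dis35cki = 10`) is switched on. CycD bound in the
  CycD–Cdk5–p27 trimer is protected from turnover (a slower degradation
  rate), reflecting the stabilizing role of p27 in that complex.
* In module 3, mono-phosphorylated Rb binds E2F with partial weight
  (`r1_bind = 0.3`, configurable). With full binding the system cannot
  bootstrap E2F release at any damage level; with zero binding the
  arrest state is too fragile. The partial value encodes incomplete
  repression by mono-phosphorylated Rb.

Whether amyloid-beta exports only free p27 or also the trimer is left
configurable; the default exports both with the same rate constant.

## Numerical machinery

* **Integration** uses a stiff solver (`lsoda`) at relative tolerance
  `1e-8`; trajectories are checked for finiteness, positivity (no state
  below `-1e-9`) and conservation (relative drift below `1e-6`).
* **Equilibria** are found by damped Newton iteration with central
  finite-difference Jacobians (step `1e-6 * max(1, |x|)`, residual
  tolerance `1e-9`). Conservation laws make the raw Jacobian singular, so
  the iteration runs in the affine subspace `W x = totals`; stability is
  judged from the Jacobian projected off the conserved directions.
  Equilibria outside the physical domain (negative, or beyond a
  Michaelis–Menten cycle total) are rejected; these arise as analytic
  continuations of the rate laws and are not reachable by the dynamics.
* **Bifurcation sweeps** enumerate equilibria on a control-parameter grid
  by multistart Newton (uniform levels, model anchors, and seeded
  Latin-hypercube points), warm-started between neighbouring grid values
  in an ascending and a descending pass — so a branch born anywhere in the
  range is picked up at its monostable end and followed through the whole
  window it spans. Fold detection uses the count of *stable* attractors: whenever a stable
  branch seen at the previous grid value goes missing, the sweep relaxes
  the dynamics from the old state and polishes — if the system still
  settles nearby the branch persists, and if it falls onto another
  attractor the branch has genuinely folded. Saddle nodes are refined by
  bisection to a bracketing width of `(hi - lo)/1e4`. A bistable interval
  whose lower edge coincides with the start of the scan range (zero input)
  has no deactivation fold at physical input values: the switch is
  irreversible.
* **Branch tracing** (`find_threshold`) follows one equilibrium branch
  under small control steps with adaptive step halving; a fold is declared
  when no nearby stable continuation exists at step sizes below the
  localization tolerance. Because module 2 contains a small secondary E2F
  subswitch on the resting branch, the tracer can be given a state
  predicate (for module 2: "is APC/C-Cdh1 inactivated?" — the event the
  module's saddle nodes refer to) and traces through intermediate folds
  until the relaxed post-fold state satisfies it. The toy-model tests
  cross-check traced thresholds against full sweeps.
* **Sensitivity** varies each parameter by plus and minus 10% and
  recomputes the activation threshold, reporting the fold change
  `max(new/old, old/new)` per direction and classifying parameters against
  the 2-fold criterion. A fold that disappears from the scan window is
  recorded as infinite fold change (conservative). For modules 2 and 3 the
  scan can also re-check irreversibility under every perturbation.
* **Continuation strategy.** We deliberately use dense enumeration plus
  bisection instead of pseudo-arclength continuation: for systems of this
  size (up to 12 states) it is robust, trivially verifiable against direct
  simulation, and immune to branch-switching artifacts.

Settling horizons default to 5000 time units (all shipped models settle
well before that); the battery and acceptance analyses use branch tracing
with 40 steps per scan and localization width `range/1e4`.

## Calibration and the perturbation battery

The full parameter tables behind the original study are not reproduced
here; the shipped defaults are a reconstruction calibrated so that the
entire qualitative battery passes — this calibration is part of the build,
and `module1_battery()`, `module2_battery()`, `module3_battery()` together
with `run_scenario_battery()` are the machine-checkable gate. Battery
entries encode each knockout/rescue observation as a predicate on labels,
fold presence/absence, or fold ordering. The calibrated structure:

* module 1: SN1 ≈ 0.0063, SN2 ≈ 0.0052 on amyloid-beta (both positive:
  reversible), threshold roughly doubling with the trimer-dissociation
  term on; CycD-knockout logic as described above.
* module 2: single activation fold at amyloid-beta ≈ 0.080 with no
  deactivation fold at non-negative input (irreversible); glutaminase or
  CycB knockout restore reversibility, lower the upper ROS branch and
  shift the threshold right; the double knockout and p25 inhibition
  abolish the transition; excitotoxicity (basal glutamate synthesis),
  CycB overexpression and the Cdh1 inhibitor are alternate triggers, the
  latter rescued by glutaminase inhibition.
* module 3: re-entry threshold ≈ 0.45, killer window ≈ [0.58, 1.25] on
  DNA damage, with damage levels 0 / 0.5 / 2.5 settling into the
  quiescent / repair / apoptotic states and the p21 ordering
  quiescent < apoptotic < repair.

Because the defaults are a reconstruction, the sensitivity summary is
reported in a relaxed structural form: at least 90% of all parameters
below 2-fold threshold change, with every exception confined to the
module-1 competition core (the totals and rates that directly control the
p35/CycD contest for Cdk5 and the ERK cycle). On the shipped set ~97% of
127 parameters are below 2-fold and the exceptions are the three totals
`CDKI_T`, `Cdk5_T`, `p35_T` — fixed totals are the natural sensitive knobs
of a stoichiometric competition switch. Irreversibility in modules 2 and 3
survives every individual ±10% variation.

## The transcriptome stage and its synthetic data

The eigengene pipeline summarizes a gene set per sample by the first
principal component of its gene-wise z-scored expression submatrix,
oriented so the correlation with the set's mean standardized profile is
non-negative (a convention the reference implementations share; without
it the sign of the eigengene is arbitrary). The association between the
eigengene and a sample trait is the Pearson correlation with the Student
asymptotic p value (`t = r sqrt(n-2)/sqrt(1-r^2)` on `n-2` degrees of
freedom); for a binary disease label this is the point-biserial
correlation. Quantile normalization (each column forced to the mean
order-statistic distribution, ties averaged) and `log2(x+1)` are available
as preprocessing, matching standard practice for cross-platform
expression matrices. Gene identifiers absent from the matrix are dropped
with a warning; curated target lists are taken as given inputs.

The synthetic-data generator emulates exactly the structure this analysis
assumes: a balanced binary trait, per-set factors with an *exact* sample
correlation against the trait (projection construction: a normal vector is
orthogonalized against the standardized trait and recombined as
`r t + sqrt(1-r^2) z`), set genes as `loading x factor + N(0, noise_sd)`,
and pure-noise background genes. It does not emulate platform artifacts —
probe effects, batch structure, heavy-tailed noise, or correlated
background genes — so passing tests demonstrate correctness of the
method's implementation, not robustness to real-data pathologies. Default
noise (`noise_sd = 0.3` at unit loading) is comfortably below the level at
which a 50-gene module would become unrecoverable, which is the regime the
method is meant for.

## Problem sizes and numerical choices

The shipped analyses use: 40-step branch traces for thresholds; sweeps
with at least 50 grid points and `range/1e4` fold localization; ±10%
sensitivity over all 127 parameters of the three modules; 10^4 null
replicates at n = 30 for the type-I error of the asymptotic p value; and a
200 x 100 expression matrix with a 50-gene planted module for recovery
checks. These sizes make every headline quantity reproducible on a single
CPU in minutes while leaving the fold-localization accuracy (absolute
error well below 1e-3 on the toy oracles) far tighter than any claim made
about the biology.

## Known limitations

* The three modules are deliberately uncoupled, as in the source study;
  crosstalk (e.g. module-1 CycD accumulation feeding module-2 p35
  cleavage) is discussed there as hypothesis only and is out of scope, as
  are Akt/BAD/FOXO1 signalling, DREAM-complex regulation, explicit
  tau/amyloid production, and decaying (repaired) DNA damage — a decay
  option exists but is off by default.
* Compartment volumes in module 1 are assumed equal, so nuclear and
  cytosolic concentrations are directly comparable.
* Parameter values are a calibrated reconstruction; quantitative fold
  locations are meaningful relative to each other, not as measurements.
* The equilibrium analyses cover saddle-node structure only; there are no
  oscillatory regimes in these models by construction, and the engine does
  not attempt Hopf or orbit continuation.
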