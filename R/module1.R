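# Module 1: amyloid-beta driven competition between cyclin D and p35 for
# Cdk5, p27 nucleocytoplasmic shuttling, and the bistable ERK switch.
#
# Mechanism encoded:
#   * In resting neurons p27 (CDKI) is nuclear and holds p35-Cdk5 in a
#     nuclear trimer; the free cytosolic p35-Cdk5 dimer represses MEK and
#     keeps ERK activity low.
#   * Amyloid-beta drives nuclear export of p27 (free and trimer alike).
#     Cytosolic p27 stabilizes the otherwise weak CycD-Cdk5 complex, so CycD
#     competes p35 away from Cdk5; cytosolic p35-Cdk5 falls and ERK fires.
#   * Active ERK drives CycD synthesis, closing the positive feedback loop
#     that makes the switch bistable.
#   * An optional direct amyloid-beta effect dissociates the p35-Cdk5-p27
#     trimer (k_dis35cki; 0 by default, 10 in the rescue variant).
# All complex association/dissociation is fast mass action (>= 10x the
# synthesis/degradation/transport scale), so the p27, p35 and Cdk5 totals
# are honest ODE-level conserved quantities. ERK interconversion is
# Michaelis-Menten with small Michaelis constants (zero-order capable).

#' Default parameter set for the ERK-switch module
#'
#' Values are a calibrated reconstruction: rate constants in inverse time
#' (a.u.), totals and Michaelis constants dimensionless. All parameters can
#' be overridden, or loaded from a `m1.*` config namespace via
#' [read_params()].
#'
#' @param ... Named overrides of individual defaults.
#' @return Named numeric vector.
#' @export
module1_params <- function(...) {
  p <- c(
    Abeta      = 0,      # input: amyloid-beta level (a.u.)
    # totals (dimensionless)
    CDKI_T     = 1.2,    # p27
    p35_T      = 1,
    Cdk5_T     = 0.9,
    ERK_T      = 1,
    # complex formation (fast mass action)
    ka_pc      = 100,    # p35 + Cdk5 association
    kd_pc      = 1,      # p35-Cdk5 dissociation
    ka_cki     = 28,     # p35-Cdk5 + p27 trimer association
    kd_cki     = 0.12,   # trimer dissociation
    ka_cycd    = 100,    # CycD + Cdk5 association
    kd_cycd5   = 25,     # CycD-Cdk5 dissociation (weak without p27)
    ka_ckid    = 100,    # CycD-Cdk5 + p27 association
    kd_ckid    = 0.01,   # CycD-Cdk5-p27 dissociation (p27-stabilized)
    k_dis35cki = 0,      # amyloid-beta driven trimer dissociation (rescue: 10)
    # p27 nucleocytoplasmic transport
    k_excki0   = 0.01,   # basal nuclear export of free p27
    k_excki    = 10,     # amyloid-beta dependent export (x Abeta)
    k_incki    = 1.2,    # nuclear import of free p27
    k_ext0     = 0.01,   # basal trimer export
    k_ext      = 10,     # amyloid-beta dependent trimer export (x Abeta)
    k_int      = 1,      # trimer import (p27 compartmentalizes p35-Cdk5)
    # p35-Cdk5 dimer shuttling (Cdk5 is intrinsically cytosolic)
    k_expc     = 1,
    k_inpc     = 0.02,
    # CycD turnover
    k_scycdb   = 0.001,  # basal synthesis
    k_scycd    = 0.9,    # ERK-driven synthesis (x ERK_active)
    k_dcycd    = 0.1,    # degradation of free CycD and CycD-Cdk5
    k_dcycdk   = 0.005,  # degradation of CycD inside CycD-Cdk5-p27 (p27-protected)
    # ERK interconversion (Michaelis-Menten, ultrasensitive)
    k_aerk     = 2,      # activation (MEK-driven)
    k_ierk     = 0.7,    # inactivation
    J_aerk     = 0.05,
    J_ierk     = 0.05,
    k_mek35    = 100     # MEK repression by cytosolic p35-Cdk5
  )
  ov <- c(...)
  if (length(ov)) {
    stopifnot(all(names(ov) %in% names(p)))
    p[names(ov)] <- ov
  }
  p
}

#' Build the ERK-switch model (module 1)
#'
#' States: free p27 in nucleus/cytosol (`CKIn`, `CKIc`), p35-Cdk5 dimer
#' (`PCn`, `PCc`), p35-Cdk5-p27 trimer (`Tn`, `Tc`), free p35 (`P35`), free
#' Cdk5 (`CDK5`), cytosolic CycD (`D`), CycD-Cdk5 (`DC`), CycD-Cdk5-p27
#' (`DCK`), and active ERK (`ERKa`; inactive ERK is `ERK_T - ERKa`).
#' Auxiliary outputs: total CycD (`CycD_Total`), cytosolic p35-Cdk5 activity
#' (`PC_activity`, the MEK repressor), MEK availability (`mek`).
#'
#' Conserved totals: all p27-containing species sum to `CDKI_T`, all
#' p35-containing species to `p35_T`, all Cdk5-containing species to
#' `Cdk5_T`.
#'
#' @param params Parameter set from [module1_params()].
#' @return A [model_spec()] with input parameter `Abeta`.
#' @export
build_module1 <- function(params = module1_params()) {
  req <- names(module1_params())
  missing <- setdiff(req, names(params))
  if (length(missing)) {
    stop_config("module 1 parameters missing: ", paste(missing, collapse = ", "))
  }
  if (params[["ERK_T"]] <= 0) {
    stop_config("ERK_T must be positive (appears in the ERK cycle divisor)")
  }
  states <- c("CKIn", "CKIc", "Tn", "Tc", "PCn", "PCc", "P35", "CDK5",
              "D", "DC", "DCK", "ERKa")

  aux <- c(
    kex_eff  = "k_excki0 + k_excki * Abeta",
    kext_eff = "k_ext0 + k_ext * Abeta",
    mek      = "1 / (1 + k_mek35 * PCc)",
    PC_activity = "PCc",
    CycD_Total  = "D + DC + DCK")

  rhs <- c(
    CKIn = "-kex_eff * CKIn + k_incki * CKIc - ka_cki * PCn * CKIn +
            kd_cki * Tn + k_dis35cki * Abeta * Tn",
    CKIc = "kex_eff * CKIn - k_incki * CKIc - ka_cki * PCc * CKIc +
            kd_cki * Tc + k_dis35cki * Abeta * Tc -
            ka_ckid * DC * CKIc + kd_ckid * DCK + k_dcycdk * DCK",
    Tn   = "ka_cki * PCn * CKIn - kd_cki * Tn - k_dis35cki * Abeta * Tn -
            kext_eff * Tn + k_int * Tc",
    Tc   = "ka_cki * PCc * CKIc - kd_cki * Tc - k_dis35cki * Abeta * Tc +
            kext_eff * Tn - k_int * Tc",
    PCn  = "kd_cki * Tn + k_dis35cki * Abeta * Tn - ka_cki * PCn * CKIn +
            k_inpc * PCc - k_expc * PCn",
    PCc  = "ka_pc * P35 * CDK5 - kd_pc * PCc + kd_cki * Tc +
            k_dis35cki * Abeta * Tc - ka_cki * PCc * CKIc -
            k_inpc * PCc + k_expc * PCn",
    P35  = "-ka_pc * P35 * CDK5 + kd_pc * PCc",
    CDK5 = "-ka_pc * P35 * CDK5 + kd_pc * PCc - ka_cycd * D * CDK5 +
            kd_cycd5 * DC + k_dcycd * DC + k_dcycdk * DCK",
    D    = "k_scycdb + k_scycd * ERKa - k_dcycd * D - ka_cycd * D * CDK5 +
            kd_cycd5 * DC",
    DC   = "ka_cycd * D * CDK5 - kd_cycd5 * DC - ka_ckid * DC * CKIc +
            kd_ckid * DCK - k_dcycd * DC",
    DCK  = "ka_ckid * DC * CKIc - kd_ckid * DCK - k_dcycdk * DCK",
    ERKa = "k_aerk * mek * (ERK_T - ERKa) / (J_aerk + ERK_T - ERKa) -
            k_ierk * ERKa / (J_ierk + ERKa)")
  rhs <- gsub("\\s+", " ", rhs)

  conserved <- list(
    list(label = "p27_total",
         weights = c(CKIn = 1, CKIc = 1, Tn = 1, Tc = 1, DCK = 1),
         total = "CDKI_T"),
    list(label = "p35_total",
         weights = c(P35 = 1, PCn = 1, PCc = 1, Tn = 1, Tc = 1),
         total = "p35_T"),
    list(label = "Cdk5_total",
         weights = c(CDK5 = 1, PCn = 1, PCc = 1, Tn = 1, Tc = 1,
                     DC = 1, DCK = 1),
         total = "Cdk5_T"))

  init <- c(CKIn = unname(params[["CDKI_T"]]), CKIc = 0, Tn = 0, Tc = 0,
            PCn = 0, PCc = 0, P35 = unname(params[["p35_T"]]),
            CDK5 = unname(params[["Cdk5_T"]]), D = 0, DC = 0, DCK = 0,
            ERKa = 0)

  model_spec("module1_erk", states, params, rhs, aux = aux,
             conserved = conserved, input_param = "Abeta", init = init,
             anchors = module1_anchors(params), nonneg = TRUE,
             upper = c(ERKa = "ERK_T"))
}

# rough resting / pathological state guesses used to seed multistart
module1_anchors <- function(p) {
  ckit <- unname(p[["CDKI_T"]]); p35t <- unname(p[["p35_T"]])
  cdk5t <- unname(p[["Cdk5_T"]]); erkt <- unname(p[["ERK_T"]])
  pool <- min(p35t, cdk5t)
  rest <- c(CKIn = max(ckit - 0.5 * pool, 0), CKIc = 0,
            Tn = 0.5 * pool, Tc = 0,
            PCn = 0, PCc = 0.5 * pool,
            P35 = max(p35t - pool, 0), CDK5 = max(cdk5t - pool, 0),
            D = 0, DC = 0, DCK = 0, ERKa = 0.02 * erkt)
  # pathological guess: most Cdk5 sequestered in CycD-Cdk5-p27; built to
  # satisfy the conserved totals exactly
  dck <- 0.6 * min(ckit, cdk5t)
  pcc <- 0.02 * pool
  dc <- 0.02 * cdk5t
  ckic <- 0.1 * ckit
  path <- c(CKIn = max(ckit - dck - ckic, 0), CKIc = ckic, Tn = 0, Tc = 0,
            PCn = 0, PCc = pcc,
            P35 = max(p35t - pcc, 0),
            CDK5 = max(cdk5t - dck - pcc - dc, 0),
            D = 2, DC = dc, DCK = dck, ERKa = 0.9 * erkt)
  list(rest = rest, path = path)
}

#' Classify a module-1 state as normal or pathological
#'
#' ERK hyperactivity (together with CycD accumulation) marks the
#' pathological, cell-cycle re-entry prone state. Classification is by
#' thresholding active ERK at the midpoint between the two stable-branch
#' values of the reference diagram (default 0.5 x `ERK_T`), configurable.
#'
#' @param state An `equilibrium`, a named state vector, or a `trajectory`
#'   (classified at its final state).
#' @param thresholds List with element `erk` (threshold on `ERKa`).
#' @param params Module-1 parameters (for the `ERK_T` default).
#' @return `"normal"` or `"pathological"`.
#' @export
classify_module1 <- function(state, thresholds = NULL,
                             params = module1_params()) {
  x <- as_state_vector(state)
  thr <- (thresholds$erk %||% (0.5 * unname(params[["ERK_T"]])))
  if (x[["ERKa"]] > thr) "pathological" else "normal"
}

as_state_vector <- function(state) {
  if (inherits(state, "equilibrium")) return(state$state)
  if (inherits(state, "trajectory")) return(final_state(state))
  state
}

#' Preset perturbation scenarios for module 1
#'
#' Knockouts follow the standard convention: synthesis/activation rate set
#' to zero, or a fixed total set to zero.
#'
#' @return Named list of [scenario()] objects: `p27_KO`, `CycD_KO`,
#'   `MEK_inhibition`, `p35_overexpression`, `trimer_dissociation_on`.
#' @export
module1_scenarios <- function() {
  list(
    p27_KO = scenario("p27_KO", list(CDKI_T = 0),
      "p27 silencing: no CDKI anywhere; CycD cannot sequester Cdk5",
      expect = "low ERK under amyloid-beta"),
    CycD_KO = scenario("CycD_KO", list(k_scycd = 0, k_scycdb = 0),
      "CycD knockout: ERK-driven and basal CycD synthesis off",
      expect = "blocks high ERK only with trimer dissociation on"),
    MEK_inhibition = scenario("MEK_inhibition", list(k_aerk = 0),
      "MEK inhibitor: ERK activation rate zero",
      expect = "monostable low ERK"),
    p35_overexpression = scenario("p35_overexpression", list(p35_T = 2),
      "p35 doubled: stronger ERK repression",
      expect = "higher amyloid-beta threshold"),
    trimer_dissociation_on = scenario("trimer_dissociation_on",
      list(k_dis35cki = 10),
      "direct amyloid-beta destabilization of the p35-Cdk5-p27 trimer",
      expect = "right-shifted threshold, delayed ERK activation"))
}
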