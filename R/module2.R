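# Module 2: calcium/calpain/p25-Cdk5 inactivation of Rb and APC/C-Cdh1,
# glutaminase and cyclin B feedback loops, and the irreversible
# oxidative-stress switch.
#
# Wiring encoded:
#   * Amyloid-beta and glutamate drive Ca2+ influx; Ca2+ activates calpain
#     with cooperativity 2; calpain cleaves p35 (fixed parameter) into p25,
#     whose slower turnover raises Cdk5 activity.
#   * p25-Cdk5 and CycB-Cdk1 phosphorylate (inactivate) Rb and APC/C-Cdh1
#     (Michaelis-Menten interconversion of normalized fractions).
#   * Active Cdh1 degrades CycB and glutaminase (Gls1) and supports NADPH
#     (direct stand-in for the Pfkfb3/pentose-phosphate/glutathione route).
#   * Rb hyperphosphorylation frees E2F (Hill autoactivation), E2F drives
#     CycB (Hill): mutual antagonism CycB-Cdk1 -| Cdh1 -| CycB-Cdk1.
#   * Cdh1 -| Gls1 -> glutamate -> Ca2+ -> p25 -| Cdh1 closes the second
#     loop; ROS is produced by a CycB-dependent, Ca2+-gated source, scavenged
#     in proportion to NADPH, and feeds back onto Ca2+ (mutual
#     amplification, saturable).
# High ROS marks the pathological state; with both feedback loops intact
# the transition is irreversible with respect to amyloid-beta.

#' Default parameter set for the redox-switch module
#'
#' @param ... Named overrides of individual defaults.
#' @return Named numeric vector.
#' @export
module2_params <- function(...) {
  p <- c(
    Abeta      = 0,      # input: amyloid-beta level (a.u.)
    p35        = 1,      # cleavage substrate level (fixed parameter)
    Rb_T       = 1,
    Cdh1_T     = 1,
    # calcium
    k_scab     = 0.002,  # basal Ca2+ influx
    k_sca      = 2.5,    # amyloid-beta driven influx (x Abeta)
    k_glu      = 0.5,    # glutamate-driven influx (x GLU)
    k_caros    = 0.3,    # ROS -> Ca2+ amplification (saturable)
    J_caros    = 2,      # half-saturation of the ROS term
    k_dca      = 1,
    # calpain (Hill, n = 2)
    k_acap     = 1,
    k_icap     = 0.5,
    J_cap      = 0.5,
    n_calpain  = 2,
    # p25 (slow turnover relative to cleavage flux)
    k_sp25     = 0.15,   # calpain-dependent cleavage of p35
    k_dp25     = 0.05,
    # Rb phosphorylation cycle (MM fractions)
    k_irb      = 1,      # x (p25 + e_cb2 * CycB)
    e_cb2      = 0.3,
    k_arb      = 0.3,
    J_irb      = 0.05,
    J_arb      = 0.05,
    # Cdh1 (in)activation cycle
    k_acdh1    = 1,
    k_icdh1    = 1,      # x (p25 + e_cb * CycB)
    e_cb       = 0.35,
    J_acdh     = 0.05,
    J_icdh     = 0.05,
    # E2F (Hill autoactivation gated by RbPP)
    k_se2fb    = 0.05,
    k_se2f     = 0.3,
    J_e2f      = 0.5,
    k_de2f     = 0.1,
    # CycB
    k_scycb    = 0.01,   # basal synthesis
    k_scyc     = 0.2,    # E2F-driven synthesis (Hill)
    J_cycb     = 0.5,
    k_dcycb    = 0.05,
    k_dcycbc   = 1,      # Cdh1-dependent degradation
    # glutaminase / glutamate
    k_sgls     = 0.1,
    k_dgls     = 0.05,
    k_dglsc    = 2,      # Cdh1-dependent degradation
    k_sglub    = 0.01,   # basal glutamate synthesis (excitotoxicity dial)
    k_sglu     = 1,      # Gls1-driven glutamate synthesis
    k_dglu     = 1,
    # NADPH (antioxidant capacity)
    k_anadphb  = 0.05,   # basal (antioxidant dial)
    k_anadph   = 0.5,    # Cdh1-supported
    k_dnadph   = 0.5,
    # ROS
    k_srosb    = 0.005,
    k_srosca   = 0.55,   # Ca2+-gated production (mitochondrial dysfunction)
    k_sroscb   = 0.3,    # CycB-Cdk1 driven production (ETC electron leak)
    J_rosca    = 2,      # Ca2+ gate half-saturation
    k_dros     = 1       # scavenging x NADPH
  )
  ov <- c(...)
  if (length(ov)) {
    stopifnot(all(names(ov) %in% names(p)))
    p[names(ov)] <- ov
  }
  p
}

#' Build the redox-switch model (module 2)
#'
#' States: `Ca` (intracellular calcium), `Cap` (calpain activity fraction),
#' `P25` (p25-Cdk5 activity), `RbPP` (hyperphosphorylated, inactive Rb
#' fraction), `Cdh1dp` (dephosphorylated, active APC/C-Cdh1 fraction),
#' `E2F`, `CycB` (CycB-Cdk1 activity), `Gls` (glutaminase), `Glu`
#' (glutamate), `NADPH`, `ROS`. Fractions are bounded by their totals.
#'
#' @param params Parameter set from [module2_params()].
#' @return A [model_spec()] with input parameter `Abeta`.
#' @export
build_module2 <- function(params = module2_params()) {
  req <- names(module2_params())
  missing <- setdiff(req, names(params))
  if (length(missing)) {
    stop_config("module 2 parameters missing: ", paste(missing, collapse = ", "))
  }
  states <- c("Ca", "Cap", "P25", "RbPP", "Cdh1dp", "E2F", "CycB",
              "Gls", "Glu", "NADPH", "ROS")
  aux <- c(
    hill_ca  = "Ca^n_calpain / (J_cap^n_calpain + Ca^n_calpain)",
    kin_rb   = "k_irb * (P25 + e_cb2 * CycB)",
    kin_cdh  = "k_icdh1 * (P25 + e_cb * CycB)",
    ros_gate = "Ca^2 / (J_rosca^2 + Ca^2)")
  rhs <- c(
    Ca     = "k_scab + k_sca * Abeta + k_glu * Glu +
              k_caros * ROS^2 / (J_caros^2 + ROS^2) - k_dca * Ca",
    Cap    = "k_acap * hill_ca * (1 - Cap) - k_icap * Cap",
    P25    = "k_sp25 * Cap * p35 - k_dp25 * P25",
    RbPP   = "kin_rb * (Rb_T - RbPP) / (J_irb + Rb_T - RbPP) -
              k_arb * RbPP / (J_arb + RbPP)",
    Cdh1dp = "k_acdh1 * (Cdh1_T - Cdh1dp) / (J_acdh + Cdh1_T - Cdh1dp) -
              kin_cdh * Cdh1dp / (J_icdh + Cdh1dp)",
    E2F    = "(k_se2fb + k_se2f * E2F^2 / (J_e2f^2 + E2F^2)) * RbPP / Rb_T -
              k_de2f * E2F",
    CycB   = "k_scycb + k_scyc * E2F^2 / (J_cycb^2 + E2F^2) -
              (k_dcycb + k_dcycbc * Cdh1dp) * CycB",
    Gls    = "k_sgls - (k_dgls + k_dglsc * Cdh1dp) * Gls",
    Glu    = "k_sglub + k_sglu * Gls - k_dglu * Glu",
    NADPH  = "k_anadphb + k_anadph * Cdh1dp - k_dnadph * NADPH",
    ROS    = "k_srosb + k_sroscb * CycB + k_srosca * ros_gate -
              k_dros * NADPH * ROS")
  rhs <- gsub("\\s+", " ", rhs)

  init <- c(Ca = 0.01, Cap = 0, P25 = 0, RbPP = 0,
            Cdh1dp = unname(params[["Cdh1_T"]]), E2F = 0, CycB = 0,
            Gls = 0.05, Glu = 0.05, NADPH = 1, ROS = 0.01)

  anchors <- list(
    rest = init,
    path = c(Ca = 2, Cap = 0.7, P25 = 2, RbPP = unname(params[["Rb_T"]]),
             Cdh1dp = 0, E2F = 2, CycB = 4, Gls = 2, Glu = 2,
             NADPH = 0.1, ROS = 10))

  model_spec("module2_redox", states, params, rhs, aux = aux,
             input_param = "Abeta", init = init, anchors = anchors,
             nonneg = TRUE,
             upper = c(Cap = 1, RbPP = "Rb_T", Cdh1dp = "Cdh1_T"))
}

#' Classify a module-2 state as normal or pathological
#'
#' High ROS marks the pathological (oxidative stress) state.
#'
#' @param state An `equilibrium`, named state vector, or `trajectory`.
#' @param thresholds List with element `ros` (default 1).
#' @return `"normal"` or `"pathological"`.
#' @export
classify_module2 <- function(state, thresholds = NULL) {
  x <- as_state_vector(state)
  thr <- thresholds$ros %||% 1
  if (x[["ROS"]] > thr) "pathological" else "normal"
}

#' Preset perturbation scenarios for module 2
#'
#' @return Named list of [scenario()] objects: `gls_KO`, `cycb_KO`,
#'   `p25_inhibition`, `double_KO`, `cdh1_inhibitor`, `antioxidant`,
#'   `glutamate_excitotoxicity`, `cycb_overexpression`.
#' @export
module2_scenarios <- function() {
  list(
    gls_KO = scenario("gls_KO", list(k_sgls = 0),
      "glutaminase knockout: Cdh1->Gls->glutamate->Ca loop broken",
      expect = "reversible transition, lower ROS branch, SN1 right"),
    cycb_KO = scenario("cycb_KO", list(k_scycb = 0, k_scyc = 0),
      "CycB knockout: CycB-Cdh1 mutual antagonism broken",
      expect = "reversible transition, lower ROS branch, SN1 right"),
    p25_inhibition = scenario("p25_inhibition", list(k_sp25 = 0),
      "p25-Cdk5 inhibition: no cleavage product",
      expect = "no pathological transition"),
    double_KO = scenario("double_KO",
      list(k_sgls = 0, k_scycb = 0, k_scyc = 0),
      "glutaminase AND CycB knockout",
      expect = "no pathological transition"),
    cdh1_inhibitor = scenario("cdh1_inhibitor", list(k_acdh1 = 0),
      "APC/C-Cdh1 inhibitor: activation rate zero",
      expect = "pathological state without amyloid-beta"),
    antioxidant = scenario("antioxidant", list(k_anadphb = 2),
      "membrane-permeable antioxidant: basal scavenging capacity raised",
      expect = "normal state despite amyloid-beta"),
    glutamate_excitotoxicity = scenario("glutamate_excitotoxicity",
      list(k_sglub = 1),
      "excess basal glutamate synthesis",
      expect = "pathological transition without amyloid-beta"),
    cycb_overexpression = scenario("cycb_overexpression",
      list(k_scycb = 2),
      "CycB overexpression",
      expect = "pathological transition without amyloid-beta"))
}
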