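# Module 3: DNA damage-driven CycD/E2F activation against a p21 barrier,
# with p53 helper-to-killer conversion gated by p53DINP1. Two separated
# bistable switches emerge: cell-cycle re-entry (E2F, irreversible) at a
# lower damage threshold and apoptosis (p53 killer) at a higher one.
#
# Wiring encoded:
#   * Damage boosts CycD synthesis, stabilizes E2F (degradation divided by
#     1 + fac2 * damage), reduces p53 degradation and accelerates Mdm2
#     turnover (ARF compressed into the damage dependence).
#   * A three-state Rb chain (hypo -> mono via CycD-Cdk4/6 -> hyper via
#     CycE-Cdk2); only non-hyperphosphorylated Rb binds E2F
#     stoichiometrically (smooth quadratic binding formula).
#   * Cyclins (CycD + CycE) are stoichiometrically buffered by p21 (CDKI);
#     only the free fraction carries kinase activity, so activity compares
#     CycD_Total + CycE_Total against CDKI_Total.
#   * E2F drives CycE and SCF-Skp2 (Ubl); p21 is made by p53 helper and
#     degraded in a CycE-Cdk2/Ubl-dependent way -> the re-entry loop
#     (E2F -> CycE -> RbPP -> E2F, plus p21 destruction) is self-sustaining
#     once engaged: the E2F switch has no deactivation fold at
#     non-negative damage.
#   * p53DINP1 is a Hill function of E2F and p53 killer; helper-to-killer
#     conversion is a Hill function of p53DINP1 -> the killer switch is
#     bistable with both folds at positive damage.

#' Default parameter set for the DNA-damage module
#'
#' @param ... Named overrides of individual defaults.
#' @return Named numeric vector.
#' @export
module3_params <- function(...) {
  p <- c(
    DNA_damage = 0,      # input (a.u.)
    Rb_T       = 1,
    # damage coupling
    k_sddd     = 8,      # damage boost of CycD synthesis
    fac2       = 1,      # damage-dependent E2F stabilization factor
    k_dam53    = 4,      # damage reduction of p53 degradation
    k_damm     = 0.5,    # damage acceleration of Mdm2 degradation
    # cyclins
    k_sd       = 0.04,   # CycD synthesis (x (1 + k_sddd * damage))
    k_dd       = 0.12,
    k_seb      = 0.002,  # basal CycE synthesis
    k_se       = 0.12,   # E2F-driven CycE synthesis
    k_de       = 0.1,
    # Rb phosphorylation chain (MM)
    k_pm       = 1,      # CycD-Cdk4/6 monophosphorylation
    k_dpm      = 0.25,
    k_ph       = 1.5,    # CycE-Cdk2 hyperphosphorylation
    k_dph      = 0.25,
    J_pm       = 0.1, J_dpm = 0.1, J_ph = 0.1, J_dph = 0.1,
    # E2F total
    k_sfb      = 0.02,
    k_sf       = 0.2,    # autoactivation (Hill on free E2F)
    J_f        = 0.15,
    k_df       = 0.1,    # divided by (1 + fac2 * damage)
    K_fe       = 0.01,   # Rb:E2F binding dissociation constant
    r1_bind    = 0.3,    # E2F-binding weight of monophosphorylated Rb
    # Ubl (SCF-Skp2)
    k_subl     = 0.2,
    k_dubl     = 0.2,
    # p21 (CDKI)
    k_s21b     = 0.01,
    k_s21      = 0.05,   # p53-helper-driven synthesis
    k_d21      = 0.05,
    k_d21e     = 0.03,   # CycE-Cdk2/Ubl-dependent degradation (saturable)
    J_21e      = 1,      # half-saturation of the CycE/Ubl term
    K_ck       = 0.01,   # cyclin:CDKI binding dissociation constant
    # p53 / Mdm2
    k_s53      = 0.1,
    k_d53      = 0.5,    # x Mdm2, divided by (1 + k_dam53 * damage)
    k_smb      = 0.04,
    k_sm53     = 0.02,   # p53-driven Mdm2 synthesis
    k_dm       = 0.1,    # x (1 + k_damm * damage)
    # killer conversion via p53DINP1
    k_kill     = 0.5,    # helper -> killer, Hill in DINP1
    J_kill     = 0.5,
    n_kill     = 4,
    k_help     = 0.25,   # killer -> helper back conversion
    kd53k_fac  = 3,      # killer degrades faster than helper (x k_d53)
    k_sdinpb   = 0.001,
    k_sdinp    = 0.2,    # Hill drive from E2F + killer
    w_f        = 0.1,    # E2F weight in the DINP1 drive
    w_k        = 1.3,    # killer weight (positive feedback)
    J_dinp     = 1,
    n_dinp     = 4,
    k_ddinp    = 0.1
  )
  ov <- c(...)
  if (length(ov)) {
    stopifnot(all(names(ov) %in% names(p)))
    p[names(ov)] <- ov
  }
  p
}

#' Build the DNA-damage model (module 3)
#'
#' States: `CycD`, `CycE`, `P21` (CDKI_Total), `FT` (total E2F), Rb chain
#' `R0` (hypo), `R1` (mono), `R2` (hyper, RbPP), `UBL` (SCF-Skp2), `P53h`
#' (helper), `P53k` (killer), `MDM2`, `DINP` (p53DINP1). Auxiliary outputs:
#' `E2F_free` (unbound E2F from the quadratic binding formula with
#' non-hyperphosphorylated Rb), `CycFree` (cyclins not buffered by p21),
#' `Dact`/`Eact` (CycD-Cdk4/6 and CycE-Cdk2 activities), `p53a_T`
#' (helper + killer).
#'
#' The Rb chain is conserved: `R0 + R1 + R2 = Rb_T`.
#'
#' @param params Parameter set from [module3_params()].
#' @return A [model_spec()] with input parameter `DNA_damage`.
#' @export
build_module3 <- function(params = module3_params()) {
  req <- names(module3_params())
  missing <- setdiff(req, names(params))
  if (length(missing)) {
    stop_config("module 3 parameters missing: ", paste(missing, collapse = ", "))
  }
  states <- c("CycD", "CycE", "P21", "FT", "R0", "R1", "R2", "UBL",
              "P53h", "P53k", "MDM2", "DINP")
  aux <- c(
    RbA     = "R0 + r1_bind * R1",
    E2F_free = "0.5 * (FT - RbA - K_fe +
                sqrt((FT - RbA - K_fe)^2 + 4 * K_fe * FT))",
    CycT    = "CycD + CycE",
    CycFree = "0.5 * (CycT - P21 - K_ck +
               sqrt((CycT - P21 - K_ck)^2 + 4 * K_ck * CycT))",
    freefrac = "CycFree / (CycT + 1e-12)",
    Dact    = "CycD * freefrac",
    Eact    = "CycE * freefrac",
    g53     = "1 / (1 + k_dam53 * DNA_damage)",
    gE2F    = "1 / (1 + fac2 * DNA_damage)",
    dinp_drive = "w_f * E2F_free + w_k * P53k",
    p53a_T  = "P53h + P53k")
  rhs <- c(
    CycD = "k_sd * (1 + k_sddd * DNA_damage) - k_dd * CycD",
    CycE = "k_seb + k_se * E2F_free - k_de * CycE",
    P21  = "k_s21b + k_s21 * P53h -
            (k_d21 + k_d21e * Eact * UBL / (J_21e + Eact * UBL)) * P21",
    FT   = "k_sfb + k_sf * E2F_free^2 / (J_f^2 + E2F_free^2) -
            k_df * gE2F * FT",
    R0   = "-k_pm * Dact * R0 / (J_pm + R0) + k_dpm * R1 / (J_dpm + R1)",
    R1   = "k_pm * Dact * R0 / (J_pm + R0) - k_dpm * R1 / (J_dpm + R1) -
            k_ph * Eact * R1 / (J_ph + R1) + k_dph * R2 / (J_dph + R2)",
    R2   = "k_ph * Eact * R1 / (J_ph + R1) - k_dph * R2 / (J_dph + R2)",
    UBL  = "k_subl * E2F_free - k_dubl * UBL",
    P53h = "k_s53 - k_d53 * MDM2 * g53 * P53h -
            k_kill * DINP^n_kill / (J_kill^n_kill + DINP^n_kill) * P53h +
            k_help * P53k",
    P53k = "k_kill * DINP^n_kill / (J_kill^n_kill + DINP^n_kill) * P53h -
            k_help * P53k - kd53k_fac * k_d53 * MDM2 * g53 * P53k",
    MDM2 = "k_smb + k_sm53 * p53a_T - k_dm * (1 + k_damm * DNA_damage) * MDM2",
    DINP = "k_sdinpb +
            k_sdinp * dinp_drive^n_dinp / (J_dinp^n_dinp + dinp_drive^n_dinp) -
            k_ddinp * DINP")
  rhs <- gsub("\\s+", " ", rhs)

  conserved <- list(
    list(label = "Rb_total", weights = c(R0 = 1, R1 = 1, R2 = 1),
         total = "Rb_T"))

  init <- c(CycD = 0, CycE = 0, P21 = 0.5, FT = 0.1,
            R0 = unname(params[["Rb_T"]]), R1 = 0, R2 = 0, UBL = 0,
            P53h = 0.1, P53k = 0, MDM2 = 0.4, DINP = 0)

  anchors <- list(
    quiescent = init,
    reentry = c(CycD = 0.5, CycE = 1.5, P21 = 0.1, FT = 2, R0 = 0.05,
                R1 = 0.1, R2 = 0.85, UBL = 1.5, P53h = 0.3, P53k = 0,
                MDM2 = 0.5, DINP = 0.05),
    apoptotic = c(CycD = 0.5, CycE = 1.5, P21 = 0.3, FT = 2, R0 = 0.05,
                  R1 = 0.1, R2 = 0.85, UBL = 1.5, P53h = 0.2, P53k = 2,
                  MDM2 = 0.5, DINP = 2))

  model_spec("module3_damage", states, params, rhs, aux = aux,
             conserved = conserved, input_param = "DNA_damage", init = init,
             anchors = anchors, nonneg = TRUE)
}

#' Classify a module-3 state as quiescent, repair or apoptotic
#'
#' Quiescent: Rb dephosphorylated, E2F sequestered. Repair: cell-cycle
#' re-entry (Rb hyperphosphorylated) with p53 in the helper state and a high
#' p21 barrier. Apoptotic: re-entry plus p53 killer accumulation.
#'
#' @param state An `equilibrium`, named state vector, or `trajectory`.
#' @param thresholds List with `rbpp` (fraction of `Rb_T`, default 0.5) and
#'   `killer` (default 0.5).
#' @param params Module-3 parameters (for `Rb_T`).
#' @return `"quiescent"`, `"repair"` or `"apoptotic"`.
#' @export
classify_module3 <- function(state, thresholds = NULL,
                             params = module3_params()) {
  x <- as_state_vector(state)
  rb_thr <- (thresholds$rbpp %||% 0.5) * unname(params[["Rb_T"]])
  k_thr <- thresholds$killer %||% 0.5
  if (x[["R2"]] < rb_thr) return("quiescent")
  if (x[["P53k"]] > k_thr) "apoptotic" else "repair"
}

#' Locate the re-entry and killer thresholds (dual-threshold analysis)
#'
#' Sweeps the damage axis and separates the folds of the two switches: the
#' E2F/cell-cycle switch (activation fold `SN1`; no deactivation fold at
#' non-negative damage) and the p53-killer switch (`SN3` activation, `SN4`
#' deactivation, both at positive damage).
#'
#' @param model A module-3 [model_spec()] (defaults allowed).
#' @param range Damage range to scan.
#' @param ... Passed to [sweep_bifurcation()].
#' @return List with `theta_e2f` (SN1 damage value or `NA`),
#'   `e2f_irreversible` (no deactivation fold at non-negative damage),
#'   `theta_killer` (`c(SN3 =, SN4 =)`, `NA` when absent) and the underlying
#'   `diagram`.
#' @export
dual_threshold_analysis <- function(model = build_module3(),
                                    range = c(0, 4), ...) {
  bd <- sweep_bifurcation(model, range = range, ...)
  sn <- bd$saddle_nodes
  # classify each fold by which switch jumps across it: killer folds move
  # P53k, re-entry folds move R2 with little killer change
  killer_fold <- vapply(seq_len(nrow(sn)), function(i) {
    st <- sn$state[[i]]
    !is.null(st) && st[["P53k"]] > 0.1
  }, TRUE)
  e2f_folds <- sn[!killer_fold, , drop = FALSE]
  k_folds <- sn[killer_fold, , drop = FALSE]
  theta_e2f <- if (nrow(e2f_folds)) min(e2f_folds$value) else NA_real_
  e2f_irrev <- nrow(e2f_folds) == 1 && length(bd$bistable_intervals) >= 1 &&
    abs(bd$bistable_intervals[[1]][1] - range[1]) < 1e-12
  sn3 <- if (nrow(k_folds)) max(k_folds$value) else NA_real_
  sn4 <- if (nrow(k_folds) >= 2) min(k_folds$value) else NA_real_
  list(theta_e2f = theta_e2f, e2f_irreversible = e2f_irrev,
       theta_killer = c(SN3 = sn3, SN4 = sn4), diagram = bd)
}

#' Preset perturbation scenarios for module 3
#'
#' @return Named list of [scenario()] objects: `fac2_up`, `p21_KO`,
#'   `dinp1_KO`.
#' @export
module3_scenarios <- function() {
  list(
    fac2_up = scenario("fac2_up", list(fac2 = 2),
      "stronger damage-dependent E2F stabilization",
      expect = "killer folds move to lower damage"),
    p21_KO = scenario("p21_KO", list(k_s21 = 0, k_s21b = 0),
      "p21 knockout: no CDKI barrier",
      expect = "re-entry without damage threshold"),
    dinp1_KO = scenario("dinp1_KO", list(k_sdinp = 0),
      "p53DINP1 knockout: killer conversion feedback off",
      expect = "no killer fold pair"))
}
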