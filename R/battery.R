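# Perturbation/rescue battery: the calibration gate for the shipped models.
#
# Each battery entry encodes one knockout/inhibitor/overexpression
# experiment together with a machine-checkable predicate on the model's
# response (a state label at a stated input, or the presence/absence/
# ordering of saddle nodes). The experimental observations these entries
# mirror are narrative; the predicate forms are this module's contribution.

#' Run a battery of perturbation scenarios
#'
#' Each entry is a list with `name`, `module`, `scenario` (a [scenario()] or
#' `NULL` for the unperturbed control), `expect` (free-text label of the
#' expected qualitative outcome) and `check`, a function taking the entry
#' and `...` and returning `list(observed = <string>, pass = <logical>)`.
#' Entries are evaluated in order; errors are caught and recorded as
#' failures.
#'
#' @param battery List of battery entries (e.g. [module1_battery()]).
#' @param file Optional path: write the report as TSV.
#' @param verbose Print one line per entry as it completes.
#' @param ... Passed through to each entry's `check`.
#' @return Data frame with columns `name`, `module`, `scenario`, `expected`,
#'   `observed`, `pass`.
#' @export
run_scenario_battery <- function(battery, file = NULL, verbose = FALSE,
                                 ...) {
  rows <- lapply(battery, function(entry) {
    res <- tryCatch(entry$check(entry, ...), error = function(e) {
      list(observed = paste0("ERROR: ", conditionMessage(e)), pass = FALSE)
    })
    if (verbose) {
      cat(sprintf("[%s] %-28s %s (%s)\n",
                  if (isTRUE(res$pass)) "ok" else "FAIL",
                  entry$name, res$observed, entry$expect))
    }
    data.frame(name = entry$name, module = entry$module,
               scenario = if (is.null(entry$scenario)) "none"
                          else entry$scenario$name,
               expected = entry$expect, observed = res$observed,
               pass = isTRUE(res$pass), stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), module = character(),
               scenario = character(), expected = character(),
               observed = character(), pass = logical())
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

battery_entry <- function(name, module, scenario, expect, check) {
  list(name = name, module = module, scenario = scenario, expect = expect,
       check = check)
}

# ---------------------------------------------------------------------------
# Shipped batteries. Thresholds are located by branch tracing
# (find_threshold / trace_branch), which the toy-model tests cross-check
# against full sweeps; full diagram sweeps are exercised separately.

# deactivation threshold: follow the activated branch from `from` down to
# `lo`; NA when the branch persists (irreversible switch)
deactivation_threshold <- function(model, control, from, lo, high_state) {
  tr <- trace_branch(model, control, from, lo, high_state)
  if (tr$reached_end) NA_real_ else tr$fold
}

# activated state just above a fold, settled from the resting state
activated_state <- function(model, control, value, init = model$init) {
  m <- model
  m$params[control] <- value
  settle(m, init = settle(model, init = init))
}

#' Perturbation battery for the ERK-switch module
#'
#' Encodes the knockout/rescue experiments for the amyloid-beta ERK switch
#' as machine-checkable predicates: bistability with both folds at positive
#' amyloid-beta, loss of bistability under MEK inhibition, the CycD-knockout
#' logic with and without direct trimer dissociation, p27-knockout rescue,
#' threshold monotonicity in the p27 total, the cusp under p35 depletion,
#' and the step response to amyloid-beta exposure.
#'
#' @param params Module-1 parameter set.
#' @return List of battery entries for [run_scenario_battery()].
#' @export
module1_battery <- function(params = module1_params()) {
  scn <- module1_scenarios()
  rng <- c(0, 0.05)
  list(
    battery_entry("m1_bistable_switch", "m1", NULL,
      "two saddle nodes with SN1 > SN2 > 0",
      function(entry, ...) {
        m <- build_module1(params)
        sn1 <- find_threshold(m, "Abeta", rng)$threshold
        hs <- activated_state(m, "Abeta", sn1 + 0.002)
        sn2 <- deactivation_threshold(set_params(m, Abeta = sn1 + 0.002),
                                      "Abeta", sn1 + 0.002, 0, hs)
        list(observed = sprintf("SN1=%.4g SN2=%.4g", sn1, sn2),
             pass = !is.na(sn1) && !is.na(sn2) && sn1 > sn2 && sn2 > 0)
      }),
    battery_entry("m1_step_response", "m1", NULL,
      "amyloid-beta step to 0.05 reaches the pathological branch",
      function(entry, ...) {
        m <- build_module1(params)
        rest <- settle(m)
        tr <- integrate_model(m, init = rest, times = seq(0, 4000, by = 10),
                              input_step = list(time = 500, param = "Abeta",
                                                value = 0.05))
        lab <- classify_module1(tr, params = params)
        cycd0 <- sum(rest[c("D", "DC", "DCK")])
        cycd1 <- sum(final_state(tr)[c("D", "DC", "DCK")])
        list(observed = sprintf("%s, CycD_Total %.3g -> %.3g",
                                lab, cycd0, cycd1),
             pass = lab == "pathological" && cycd1 > cycd0)
      }),
    battery_entry("m1_resting_state", "m1", NULL,
      "resting neuron: low ERK, p35-Cdk5 in both compartments, nuclear pool trimer-bound",
      function(entry, ...) {
        m <- build_module1(params)
        rest <- settle(m)
        cyt <- sum(rest[c("PCc", "Tc")])
        nuc <- sum(rest[c("PCn", "Tn")])
        frac_cyt <- cyt / (cyt + nuc)
        trimer_frac <- rest[["Tn"]] / max(nuc, 1e-12)
        ok <- classify_module1(rest, params = params) == "normal" &&
          frac_cyt > 0.1 && frac_cyt < 0.9 && trimer_frac > 0.8
        list(observed = sprintf("ERK %.3g, cytosolic fraction %.2f, nuclear trimer %.2f",
                                rest[["ERKa"]], frac_cyt, trimer_frac),
             pass = ok)
      }),
    battery_entry("m1_mek_inhibition", "m1", scn$MEK_inhibition,
      "monostable low ERK; bistability lost",
      function(entry, ...) {
        m <- build_module1(apply_perturbation(params, entry$scenario))
        thr <- tryCatch(find_threshold(m, "Abeta", c(0, 0.08))$threshold,
                        error = function(e) NA_real_)
        hi <- settle(set_params(m, Abeta = 0.08), init = settle(m))
        list(observed = sprintf("no activation fold: %s; ERK(0.08) = %.3g",
                                is.na(thr), hi[["ERKa"]]),
             pass = is.na(thr) && hi[["ERKa"]] < 0.3)
      }),
    battery_entry("m1_cycd_ko_without_dissociation", "m1", scn$CycD_KO,
      "high ERK still reachable (cytosolic trimer sequestration)",
      function(entry, ...) {
        m <- build_module1(apply_perturbation(params, entry$scenario))
        hi <- settle(set_params(m, Abeta = 0.08), init = settle(m))
        list(observed = sprintf("ERK(0.08) = %.3g", hi[["ERKa"]]),
             pass = hi[["ERKa"]] > 0.5)
      }),
    battery_entry("m1_cycd_ko_with_dissociation", "m1", scn$CycD_KO,
      "high ERK blocked for all scanned amyloid-beta when k_dis35cki = 10",
      function(entry, ...) {
        p <- apply_perturbation(params, entry$scenario)
        p[["k_dis35cki"]] <- 10
        m <- build_module1(p)
        r0 <- settle(m)
        erks <- vapply(c(0.02, 0.05, 0.1), function(ab) {
          settle(set_params(m, Abeta = ab), init = r0)[["ERKa"]]
        }, numeric(1))
        list(observed = sprintf("max ERK over scan = %.3g", max(erks)),
             pass = max(erks) < 0.3)
      }),
    battery_entry("m1_trimer_dissociation_shift", "m1",
      scn$trimer_dissociation_on,
      "amyloid-beta threshold shifts right with k_dis35cki = 10",
      function(entry, ...) {
        m0 <- build_module1(params)
        m10 <- build_module1(apply_perturbation(params, entry$scenario))
        sn1_0 <- find_threshold(m0, "Abeta", rng)$threshold
        sn1_10 <- find_threshold(m10, "Abeta", rng)$threshold
        list(observed = sprintf("SN1 %.4g -> %.4g", sn1_0, sn1_10),
             pass = !is.na(sn1_0) && !is.na(sn1_10) && sn1_10 > 1.1 * sn1_0)
      }),
    battery_entry("m1_p27_ko_rescue", "m1", scn$p27_KO,
      "ERK stays low under amyloid-beta without p27",
      function(entry, ...) {
        m <- build_module1(apply_perturbation(params, entry$scenario))
        hi <- settle(set_params(m, Abeta = 0.08), init = settle(m))
        list(observed = sprintf("ERK(0.08) = %.3g", hi[["ERKa"]]),
             pass = hi[["ERKa"]] < 0.3)
      }),
    battery_entry("m1_threshold_vs_p27_total", "m1", NULL,
      "SN1 decreases as CDKI_T increases",
      function(entry, ...) {
        sn <- vapply(c(1.1, 1.2, 1.3), function(ck) {
          p <- params
          p[["CDKI_T"]] <- ck
          find_threshold(build_module1(p), "Abeta", c(0, 0.08))$threshold
        }, numeric(1))
        list(observed = paste(signif(sn, 4), collapse = " > "),
             pass = all(!is.na(sn)) && all(diff(sn) < 0))
      }),
    battery_entry("m1_p35_cusp", "m1", NULL,
      "CycD requirement rises with p35_T; fold pair lost below a p35_T threshold",
      function(entry, ...) {
        thr_at <- function(p35t) {
          p <- params
          p[["p35_T"]] <- p35t
          p[["Abeta"]] <- 0.005
          m <- build_module1(p)
          tryCatch(find_threshold(m, "k_scycd", c(0, 6))$threshold,
                   error = function(e) NA_real_)
        }
        hi <- thr_at(1); mid <- thr_at(0.6); lo <- thr_at(0.15)
        # at very low p35 the ERK-repression arm is too weak: either ERK is
        # constitutively high (no fold: rest state is already activated) or
        # the threshold collapses toward zero
        p_lo <- params
        p_lo[["p35_T"]] <- 0.15
        p_lo[["Abeta"]] <- 0.005
        rest_lo <- settle(build_module1(p_lo))
        lost <- is.na(lo) || rest_lo[["ERKa"]] > 0.5
        list(observed = sprintf("k_scycd* at p35_T {1, 0.6} = {%.3g, %.3g}; low-p35 fold lost: %s",
                                hi, mid, lost),
             pass = !is.na(hi) && !is.na(mid) && hi > mid && lost)
      }))
}

#' Perturbation battery for the redox-switch module
#'
#' Encodes the calcium/ROS rescue experiments: the irreversible high-ROS
#' transition under amyloid-beta, restoration of reversibility (with a lower
#' ROS branch and right-shifted threshold) under glutaminase or CycB
#' knockout, full rescue under p25 inhibition or the double knockout, the
#' alternate excitotoxicity and CycB-overexpression triggers, the
#' APC/C-Cdh1-inhibitor route, and the antioxidant rescue.
#'
#' @param params Module-2 parameter set.
#' @return List of battery entries for [run_scenario_battery()].
#' @export
module2_battery <- function(params = module2_params()) {
  scn <- module2_scenarios()
  rng <- c(0, 0.4)
  base_model <- build_module2(params)
  # the saddle nodes of this module are the ones of APC/C-Cdh1
  # inactivation/activation, so the threshold tracer keys on the Cdh1 flip
  pathological <- function(x) x[["Cdh1dp"]] < 0.5 * params[["Cdh1_T"]]
  base_sn1 <- NULL
  get_base_sn1 <- function() {
    if (is.null(base_sn1)) {
      base_sn1 <<- find_threshold(base_model, "Abeta", rng,
                                  predicate = pathological)$threshold
    }
    base_sn1
  }
  ko_checks <- function(sc) {
    function(entry, ...) {
      m <- build_module2(apply_perturbation(params, sc))
      sn1 <- find_threshold(m, "Abeta", rng,
                            predicate = pathological)$threshold
      if (is.na(sn1)) {
        return(list(observed = "no transition found", pass = FALSE))
      }
      hs <- activated_state(m, "Abeta", min(sn1 + 0.05, rng[2]))
      sn2 <- deactivation_threshold(
        set_params(m, Abeta = min(sn1 + 0.05, rng[2])), "Abeta",
        min(sn1 + 0.05, rng[2]), 0, hs)
      # compare branch height against the unperturbed model at a matched
      # input above both thresholds
      ab_cmp <- 0.4
      hi_ko <- settle(set_params(m, Abeta = ab_cmp),
                      init = settle(m))[["ROS"]]
      hi_base <- settle(set_params(base_model, Abeta = ab_cmp),
                        init = settle(base_model))[["ROS"]]
      sn1_base <- get_base_sn1()
      list(observed = sprintf("SN1 %.3g (base %.3g), SN2 %.3g, ROS %.3g vs %.3g",
                              sn1, sn1_base, sn2, hi_ko, hi_base),
           pass = !is.na(sn2) && sn2 > 0 &&       # reversibility restored
             sn1 > sn1_base &&                    # threshold right-shifted
             hi_ko > 1 && hi_ko < hi_base)        # lower but still high
    }
  }
  list(
    battery_entry("m2_resting_state", "m2", NULL,
      "Rb and Cdh1 active; Ca, ROS, E2F targets low",
      function(entry, ...) {
        rest <- settle(base_model)
        ok <- classify_module2(rest) == "normal" &&
          rest[["Cdh1dp"]] > 0.9 * params[["Cdh1_T"]] &&
          rest[["RbPP"]] < 0.1 * params[["Rb_T"]] &&
          rest[["E2F"]] < 0.1
        list(observed = sprintf("Cdh1 %.2f RbPP %.2f ROS %.3g",
                                rest[["Cdh1dp"]], rest[["RbPP"]],
                                rest[["ROS"]]),
             pass = ok)
      }),
    battery_entry("m2_step_response", "m2", NULL,
      "amyloid-beta step flips Rb and Cdh1 together; ROS high",
      function(entry, ...) {
        rest <- settle(base_model)
        tr <- integrate_model(base_model, init = rest,
                              times = seq(0, 3000, by = 2),
                              input_step = list(time = 500, param = "Abeta",
                                                value = 0.2))
        fin <- final_state(tr)
        # 50%-crossing times of RbPP rise and Cdh1 loss
        t50 <- function(y, y0, y1) {
          mid <- (y0 + y1) / 2
          idx <- which(tr$time >= 500 &
                         (if (y1 > y0) y > mid else y < mid))[1]
          tr$time[idx]
        }
        t_rb <- t50(tr$states[, "RbPP"], tr$states[1, "RbPP"], fin[["RbPP"]])
        t_cdh <- t50(tr$states[, "Cdh1dp"], tr$states[1, "Cdh1dp"],
                     fin[["Cdh1dp"]])
        horizon <- max(tr$time) - 500
        seg <- abs(t_rb - t_cdh) / horizon
        ok <- classify_module2(fin) == "pathological" &&
          fin[["RbPP"]] > 0.9 && fin[["Cdh1dp"]] < 0.1 && seg < 0.05
        list(observed = sprintf("ROS %.3g, RP/G1S segregation %.3f of horizon",
                                fin[["ROS"]], seg),
             pass = ok)
      }),
    battery_entry("m2_irreversible_switch", "m2", NULL,
      "no deactivation fold at non-negative amyloid-beta",
      function(entry, ...) {
        sn1 <- get_base_sn1()
        hs <- activated_state(base_model, "Abeta", min(sn1 + 0.05, rng[2]))
        sn2 <- deactivation_threshold(
          set_params(base_model, Abeta = min(sn1 + 0.05, rng[2])), "Abeta",
          min(sn1 + 0.05, rng[2]), 0, hs)
        back <- settle(base_model, init = hs)
        list(observed = sprintf("SN1 %.3g, deactivation fold %s, ROS(0) %.3g",
                                sn1, ifelse(is.na(sn2), "absent", "present"),
                                back[["ROS"]]),
             pass = !is.na(sn1) && is.na(sn2) &&
               classify_module2(back) == "pathological")
      }),
    battery_entry("m2_gls_ko", "m2", scn$gls_KO,
      "reversible, lower ROS branch, right-shifted SN1",
      ko_checks(scn$gls_KO)),
    battery_entry("m2_cycb_ko", "m2", scn$cycb_KO,
      "reversible, lower ROS branch, right-shifted SN1",
      ko_checks(scn$cycb_KO)),
    battery_entry("m2_p25_inhibition", "m2", scn$p25_inhibition,
      "no pathological transition over the scanned range",
      function(entry, ...) {
        m <- build_module2(apply_perturbation(params, entry$scenario))
        r0 <- settle(m)
        ros <- vapply(c(0.2, 0.4), function(ab) {
          settle(set_params(m, Abeta = ab), init = r0)[["ROS"]]
        }, numeric(1))
        list(observed = sprintf("max ROS %.3g", max(ros)),
             pass = max(ros) < 1)
      }),
    battery_entry("m2_double_ko", "m2", scn$double_KO,
      "no pathological transition over the scanned range",
      function(entry, ...) {
        m <- build_module2(apply_perturbation(params, entry$scenario))
        r0 <- settle(m)
        ros <- vapply(c(0.2, 0.4), function(ab) {
          settle(set_params(m, Abeta = ab), init = r0)[["ROS"]]
        }, numeric(1))
        list(observed = sprintf("max ROS %.3g", max(ros)),
             pass = max(ros) < 1)
      }),
    battery_entry("m2_excitotoxicity", "m2", scn$glutamate_excitotoxicity,
      "glutamate route reproduces the irreversible transition",
      function(entry, ...) {
        thr <- find_threshold(base_model, "k_sglub",
                              c(params[["k_sglub"]], 1),
                              predicate = pathological)$threshold
        m <- build_module2(apply_perturbation(params, entry$scenario))
        hi <- settle(m)
        back <- settle(base_model, init = hi)
        list(observed = sprintf("k_sglub* = %.3g, ROS %.3g, ROS back %.3g",
                                thr, hi[["ROS"]], back[["ROS"]]),
             pass = !is.na(thr) &&
               classify_module2(hi) == "pathological" &&
               classify_module2(back) == "pathological")
      }),
    battery_entry("m2_cycb_overexpression", "m2", scn$cycb_overexpression,
      "CycB overexpression triggers the pathological state without amyloid-beta",
      function(entry, ...) {
        m <- build_module2(apply_perturbation(params, entry$scenario))
        st <- settle(m)
        list(observed = sprintf("ROS %.3g", st[["ROS"]]),
             pass = classify_module2(st) == "pathological")
      }),
    battery_entry("m2_cdh1_inhibitor", "m2", scn$cdh1_inhibitor,
      "pathological without amyloid-beta; abolished by glutaminase KO",
      function(entry, ...) {
        m <- build_module2(apply_perturbation(params, entry$scenario))
        st <- settle(m)
        p2 <- apply_perturbation(
          apply_perturbation(params, entry$scenario), scn$gls_KO)
        st2 <- settle(build_module2(p2))
        list(observed = sprintf("ROS %.3g; with gls KO %.3g",
                                st[["ROS"]], st2[["ROS"]]),
             pass = classify_module2(st) == "pathological" &&
               classify_module2(st2) == "normal")
      }),
    battery_entry("m2_antioxidant_rescue", "m2", scn$antioxidant,
      "raised scavenging capacity keeps the state normal under amyloid-beta",
      function(entry, ...) {
        m <- build_module2(apply_perturbation(params, entry$scenario))
        st <- settle(set_params(m, Abeta = 0.2), init = settle(m))
        list(observed = sprintf("ROS %.3g", st[["ROS"]]),
             pass = classify_module2(st) == "normal")
      }))
}

#' Perturbation battery for the DNA-damage module
#'
#' Encodes the dual-threshold structure: quiescent / repair / apoptotic
#' attractors at increasing damage, the ordering of the re-entry and killer
#' thresholds, irreversibility of the E2F switch, bistability of the killer
#' switch, the CDKI arrest barrier below the re-entry threshold, the p21
#' ordering across states, the fac2 left-shift of the killer folds, and
#' loss of the killer fold pair without p53DINP1 feedback.
#'
#' @param params Module-3 parameter set.
#' @return List of battery entries for [run_scenario_battery()].
#' @export
module3_battery <- function(params = module3_params()) {
  scn <- module3_scenarios()
  m0 <- build_module3(params)
  states_at <- function(dd, init) {
    settle(set_params(m0, DNA_damage = dd), init = init)
  }
  killer_sn3 <- function(m) {
    # repair branch loses stability where the killer fires
    rep_state <- settle(set_params(m, DNA_damage = 0.6),
                        init = settle(m, init = m$anchors$reentry))
    tr <- trace_branch(set_params(m, DNA_damage = 0.6), "DNA_damage",
                       0.6, 3, rep_state)
    if (tr$reached_end) NA_real_ else tr$fold
  }
  list(
    battery_entry("m3_three_attractors", "m3", NULL,
      "damage 0 / 0.5 / 2.5 give quiescent / repair / apoptotic states",
      function(entry, ...) {
        rest <- settle(m0)
        s_rep <- states_at(0.5, rest)
        s_apo <- states_at(2.5, rest)
        labs <- c(classify_module3(rest, params = params),
                  classify_module3(s_rep, params = params),
                  classify_module3(s_apo, params = params))
        p21 <- c(rest[["P21"]], s_rep[["P21"]], s_apo[["P21"]])
        ok <- identical(labs, c("quiescent", "repair", "apoptotic")) &&
          p21[3] > p21[1] && p21[3] < p21[2]   # apoptotic p21 intermediate
        list(observed = sprintf("%s; p21 = %.2f / %.2f / %.2f",
                                paste(labs, collapse = "/"),
                                p21[1], p21[2], p21[3]),
             pass = ok)
      }),
    battery_entry("m3_arrest_below_threshold", "m3", NULL,
      "CDKI barrier exceeds total cyclin activity at low damage",
      function(entry, ...) {
        rest <- settle(m0)
        aux <- model_aux(m0, rest)
        list(observed = sprintf("CDKI %.2f vs cyclins %.2f",
                                rest[["P21"]], aux[["CycT"]]),
             pass = rest[["P21"]] > aux[["CycT"]])
      }),
    battery_entry("m3_threshold_ordering", "m3", NULL,
      "theta_E2F < SN4 < SN3; E2F switch irreversible",
      function(entry, ...) {
        te <- find_threshold(m0, "DNA_damage", c(0, 2))$threshold
        sn3 <- killer_sn3(m0)
        apo <- settle(set_params(m0, DNA_damage = min(sn3 + 0.3, 3)),
                      init = m0$anchors$apoptotic)
        sn4 <- deactivation_threshold(
          set_params(m0, DNA_damage = min(sn3 + 0.3, 3)), "DNA_damage",
          min(sn3 + 0.3, 3), 0, apo)
        # E2F switch: repair branch persists to zero damage
        rep_state <- states_at(te + 0.1, settle(m0))
        tr <- trace_branch(set_params(m0, DNA_damage = te + 0.1),
                           "DNA_damage", te + 0.1, 0, rep_state)
        list(observed = sprintf("theta_E2F %.3g, SN4 %.3g, SN3 %.3g, E2F irreversible %s",
                                te, sn4, sn3, tr$reached_end),
             pass = !is.na(te) && !is.na(sn3) && !is.na(sn4) &&
               te < sn4 && sn4 < sn3 && tr$reached_end)
      }),
    battery_entry("m3_fac2_shift", "m3", scn$fac2_up,
      "stronger E2F stabilization moves the killer folds to lower damage",
      function(entry, ...) {
        sn3_0 <- killer_sn3(m0)
        m2 <- build_module3(apply_perturbation(params, entry$scenario))
        sn3_2 <- killer_sn3(m2)
        list(observed = sprintf("SN3 %.3g -> %.3g", sn3_0, sn3_2),
             pass = !is.na(sn3_0) && !is.na(sn3_2) && sn3_2 < sn3_0)
      }),
    battery_entry("m3_dinp1_ko", "m3", scn$dinp1_KO,
      "no killer fold pair without the p53DINP1 feedback",
      function(entry, ...) {
        m <- build_module3(apply_perturbation(params, entry$scenario))
        st <- settle(set_params(m, DNA_damage = 3), init = settle(m))
        list(observed = sprintf("P53k(3) = %.3g", st[["P53k"]]),
             pass = st[["P53k"]] < 0.5)
      }))
}
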