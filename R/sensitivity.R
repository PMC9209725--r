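#' Parameter sensitivity of the switching threshold
#'
#' Varies every model parameter by +10% and -10% and recomputes the location
#' of the primary saddle node (the activation threshold on the model's input
#' parameter). Sensitivity is summarized as the threshold fold change,
#' `max(new/old, old/new)`, and each parameter is classified against the
#' 2-fold criterion. When a perturbed model loses the fold entirely inside
#' the scan range the fold change is recorded as `Inf` (and counted in the
#' >= 2-fold class). Optionally the scan also checks whether the switch
#' stays irreversible under each perturbation (no deactivation fold at
#' non-negative input).
#'
#' @param model A [model_spec()] whose baseline exhibits a locatable fold on
#'   `control` within `range`.
#' @param range Scan range for the input parameter.
#' @param control Input parameter (default the model's).
#' @param delta Relative variation (default `0.10`).
#' @param params Character vector of parameters to test (default: all except
#'   the input parameter itself).
#' @param check_irreversibility If `TRUE`, additionally trace the high
#'   branch back to `range[1]` for every perturbation and flag whether no
#'   deactivation fold exists at non-negative input.
#' @param high_anchor Optional state on the high branch used to seed the
#'   irreversibility check (default: the model integrated past its baseline
#'   threshold).
#' @param predicate Optional post-fold state predicate passed to the
#'   threshold tracer (see [find_threshold()]); use it when the model has a
#'   secondary subswitch so that the scan follows the main threshold.
#' @param ... Passed to the branch tracer (`n_steps`, `jump_tol`, ...).
#' @return A `sensitivity_report`: data frame `results` with one row per
#'   (parameter, direction), columns `parameter`, `direction`, `baseline`,
#'   `perturbed`, `fold_change`, `above_2fold`, and (optionally)
#'   `irreversible`; plus `baseline_threshold`, `n_below_2fold`,
#'   `n_above_2fold` (parameter counts: a parameter is above 2-fold if
#'   either direction is).
#' @export
sensitivity_scan <- function(model, range, control = model$input_param,
                             delta = 0.10, params = NULL,
                             check_irreversibility = FALSE,
                             high_anchor = NULL, predicate = NULL, ...) {
  if (is.null(params)) params <- setdiff(names(model$params), control)
  m0 <- model
  m0$params[control] <- range[1]
  x0 <- settle(m0)
  tr0 <- trace_to_threshold(m0, control, range, x0, predicate = predicate,
                            ...)
  if (is.na(tr0$threshold)) {
    stop_config("baseline model has no locatable fold on '", control,
                "' in the given range")
  }
  theta0 <- tr0$threshold
  # a +/-10% variation rarely moves the fold by more than ~2.5x, so the
  # perturbed traces scan a narrower window (a fold escaping it is recorded
  # as fold change infinity, the conservative convention)
  hi <- min(range[2], range[1] + 3 * (theta0 - range[1]))

  if (check_irreversibility && is.null(high_anchor)) {
    high_anchor <- high_branch_state(model, control, theta0, range)
  }

  one <- function(pname, fac) {
    p <- model$params
    p[pname] <- p[pname] * fac
    p[control] <- range[1]
    # warm-start the resting branch from the baseline resting state; if
    # Newton lands on an unstable root, relax the dynamics instead
    sol <- newton_equilibrium(model, x0, p)
    if (!is.null(sol) && leading_eigenvalue(model, sol$state, p) >= 0) {
      sol <- NULL
    }
    start <- if (!is.null(sol)) sol$state else {
      m <- model
      m$params <- p
      tryCatch(settle(m), error = function(e) NULL)
    }
    if (is.null(start)) {
      return(list(perturbed = NA_real_, fold = Inf, irr = NA))
    }
    thr <- tryCatch(
      trace_to_threshold(model, control, c(range[1], hi), start,
                         params = p, predicate = predicate, ...)$threshold,
      error = function(e) NA_real_)
    fold <- if (is.na(thr)) Inf else max(abs(thr / theta0),
                                         abs(theta0 / thr))
    irr <- NA
    if (check_irreversibility && !is.na(thr)) {
      irr <- tryCatch(
        perturbed_irreversible(model, control, p, thr, range, high_anchor,
                               ...),
        error = function(e) NA)
    }
    list(perturbed = thr, fold = fold, irr = irr)
  }

  rows <- list()
  for (pname in params) {
    for (fac in c(1 + delta, 1 - delta)) {
      r <- one(pname, fac)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = pname,
        direction = if (fac > 1) "+10%" else "-10%",
        baseline = theta0, perturbed = r$perturbed,
        fold_change = r$fold,
        above_2fold = r$fold >= 2,
        irreversible = r$irr,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  per_param <- tapply(results$above_2fold, results$parameter, any)
  structure(list(results = results,
                 baseline_threshold = theta0,
                 control = control, delta = delta,
                 n_params = length(params),
                 n_above_2fold = sum(per_param),
                 n_below_2fold = sum(!per_param),
                 params_above_2fold = names(per_param)[per_param]),
            class = "sensitivity_report")
}

# a state on the activated (high) branch just above the fold
high_branch_state <- function(model, control, theta, range,
                              overshoot = 0.05) {
  m <- model
  m$params[control] <- theta + overshoot * diff(range)
  settle(m, init = model$init)
}

# does the perturbed model keep an irreversible switch? (high branch
# persists down to range[1], i.e. no deactivation fold at non-negative input)
perturbed_irreversible <- function(model, control, p, thr, range,
                                   high_anchor, ...) {
  m <- model
  m$params <- p
  m$params[control] <- min(thr + 0.05 * diff(range), range[2])
  hs <- settle(m, init = high_anchor)
  tr <- trace_branch(m, control, m$params[[control]], range[1], hs, ...)
  tr$reached_end
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report> threshold on ", x$control, " = ",
      format(x$baseline_threshold, digits = 6), "; +/-",
      100 * x$delta, "% scan of ", x$n_params, " parameters\n", sep = "")
  cat("  below 2-fold: ", x$n_below_2fold, "   >= 2-fold: ",
      x$n_above_2fold, "\n", sep = "")
  if (x$n_above_2fold) {
    cat("  >= 2-fold parameters: ",
        paste(x$params_above_2fold, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
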