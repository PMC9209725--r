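#' Define a perturbation scenario
#'
#' A scenario encodes a knockout, inhibitor or overexpression experiment as a
#' named set of parameter overrides. Following the modelling convention used
#' throughout the package, a knockout of a synthesized species sets its
#' synthesis (or activation) rate to zero, and a knockout of a species with a
#' fixed total sets that total to zero.
#'
#' @param name Scenario name.
#' @param overrides Named list or named numeric vector of parameter values.
#' @param description Free-text description of the experiment encoded.
#' @param expect Optional label of the expected qualitative outcome.
#' @return An object of class `scenario`.
#' @examples
#' gls_ko <- scenario("gls_KO", list(k_sgls = 0), "glutaminase knockout")
#' @export
scenario <- function(name, overrides = list(), description = "",
                     expect = NULL) {
  overrides <- as.list(overrides)
  if (length(overrides) &&
      (is.null(names(overrides)) || !all(nzchar(names(overrides))))) {
    stop_config("scenario overrides must be named")
  }
  vals <- vapply(overrides, function(v) as.numeric(v)[1], numeric(1))
  if (any(!is.finite(vals))) stop_config("scenario overrides must be finite")
  structure(list(name = name, overrides = vals, description = description,
                 expect = expect),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$name, "\n", sep = "")
  if (length(x$overrides)) {
    cat("  ", paste(names(x$overrides), "=", x$overrides, collapse = ", "),
        "\n", sep = "")
  }
  if (nzchar(x$description)) cat("  ", x$description, "\n", sep = "")
  invisible(x)
}

#' Apply a perturbation scenario to a parameter set
#'
#' Returns a fresh parameter set with the scenario's overrides applied; the
#' input is not modified. Every override key must exist in the parameter set.
#'
#' @param params Named numeric parameter vector.
#' @param scenario A [scenario()] (an empty scenario is the identity).
#' @return A new named numeric parameter vector.
#' @export
apply_perturbation <- function(params, scenario) {
  if (!inherits(scenario, "scenario")) {
    stop_config("`scenario` must be created with scenario()")
  }
  ov <- scenario$overrides
  if (!length(ov)) return(params)
  unknown <- setdiff(names(ov), names(params))
  if (length(unknown)) {
    stop_config("unknown parameter(s) in scenario '", scenario$name, "': ",
                paste(unknown, collapse = ", "),
                "\n  valid names: ", paste(names(params), collapse = ", "))
  }
  params[names(ov)] <- ov
  params
}

#' Apply a scenario to a model
#'
#' Convenience wrapper around [apply_perturbation()] that returns a model
#' with the perturbed parameter set.
#'
#' @param model A [model_spec()].
#' @param scenario A [scenario()].
#' @return A new `model_spec`.
#' @export
apply_scenario <- function(model, scenario) {
  model$params <- apply_perturbation(model$params, scenario)
  model
}
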