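#' Construct an ODE model specification
#'
#' A `model_spec` bundles everything the dynamics engine needs to analyse one
#' reaction network: ordered state names, a named parameter set, the
#' right-hand side of each ODE written as a plain arithmetic expression,
#' optional named auxiliary (algebraic) quantities evaluated before the
#' derivatives, conserved linear combinations of states, and the name of the
#' input parameter used as the default bifurcation control.
#'
#' All state variables are dimensionless relative concentrations and all rate
#' constants carry units of inverse time (arbitrary units), so the
#' expressions are pure arithmetic in state names, parameter names, auxiliary
#' names and `t`.
#'
#' @param name Model identifier (single string).
#' @param state_names Character vector of state variable names, in order.
#' @param params Named numeric vector of parameters. All values must be
#'   non-negative (Hill exponents, totals, rate and Michaelis constants).
#' @param rhs Named character vector, one expression per state (names must
#'   match `state_names`), giving d(state)/dt.
#' @param aux Optional named character vector of algebraic expressions
#'   evaluated in order before the derivatives (e.g. free-ligand formulas).
#' @param conserved Optional list of conservation laws, each a list with
#'   elements `label` (string), `weights` (named numeric over a subset of
#'   states) and `total` (either a parameter name or a number).
#' @param input_param Name of the parameter treated as the external input
#'   (e.g. amyloid-beta level or DNA damage).
#' @param init Named numeric vector of default initial conditions
#'   (non-negative, consistent with the conserved totals).
#' @param anchors Optional list of named state vectors used as extra
#'   starting points for multistart equilibrium searches (e.g. a resting and
#'   a pathological state estimate).
#' @param nonneg If `TRUE`, state variables are concentrations and negative
#'   equilibria are rejected as nonphysical (all shipped biology modules set
#'   this; generic toy models may have negative states).
#' @param upper Optional named character vector of state upper bounds (each
#'   a parameter name or number). Michaelis-Menten interconversion terms are
#'   only meaningful below the total of the cycle; equilibria beyond such a
#'   bound are nonphysical continuations of the rate law and are rejected.
#'
#' @return An object of class `model_spec`.
#' @examples
#' m <- model_spec("decay", "x", c(k = 1), c(x = "-k * x"), init = c(x = 1))
#' m$rhs_fun(c(x = 2), m$params)
#' @export
model_spec <- function(name, state_names, params, rhs, aux = character(),
                       conserved = list(), input_param = NULL, init = NULL,
                       anchors = list(), nonneg = FALSE, upper = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(is.character(state_names), length(state_names) >= 1L)
  if (!is_named_numeric(params)) {
    stop_config("`params` must be a uniquely named numeric vector")
  }
  if (any(!is.finite(params))) {
    stop_config("parameters must be finite: ",
                paste(names(params)[!is.finite(params)], collapse = ", "))
  }
  if (isTRUE(nonneg) && any(params < 0)) {
    # rate constants, totals and inputs of concentration models
    stop_config("parameters must be non-negative: ",
                paste(names(params)[params < 0], collapse = ", "))
  }
  if (is.null(names(rhs)) || !setequal(names(rhs), state_names) ||
      length(rhs) != length(state_names)) {
    stop_config("`rhs` must have exactly one expression per state")
  }
  rhs <- rhs[state_names]

  symbols <- unique(unlist(lapply(c(aux, rhs), function(s) {
    all.vars(parse(text = s)[[1]])
  })))
  allowed <- c(state_names, names(params), names(aux), "t", "pi")
  unknown <- setdiff(symbols, allowed)
  if (length(unknown)) {
    stop_config("unresolved symbols in model '", name, "': ",
                paste(unknown, collapse = ", "))
  }

  conserved <- lapply(conserved, function(cl) {
    stopifnot(is.list(cl), !is.null(cl$label), !is.null(cl$weights))
    if (!all(names(cl$weights) %in% state_names)) {
      stop_config("conserved law '", cl$label, "' references unknown states")
    }
    w <- numeric(length(state_names))
    names(w) <- state_names
    w[names(cl$weights)] <- cl$weights
    list(label = cl$label, weights = w, total = cl$total)
  })

  if (!is.null(input_param) && !input_param %in% names(params)) {
    stop_config("input_param '", input_param, "' is not a parameter")
  }
  if (!is.null(init)) {
    if (!is_named_numeric(init) || !setequal(names(init), state_names)) {
      stop_config("`init` must name every state exactly once")
    }
    init <- init[state_names]
    if (any(init < 0)) stop_config("initial conditions must be non-negative")
  }

  spec <- structure(
    list(name = name, state_names = state_names, params = params,
         rhs_text = rhs, aux = aux, conserved = conserved,
         input_param = input_param, init = init, anchors = anchors,
         nonneg = isTRUE(nonneg), upper = upper),
    class = "model_spec")
  spec$rhs_fun <- assemble_rhs(spec)
  spec
}

# Compile the textual RHS into an R function f(x, p, t) returning the
# derivative vector. Auxiliary quantities are evaluated first, in order.
assemble_rhs <- function(spec) {
  ns <- length(spec$state_names)
  lines <- c(
    "function(x, p, t = 0) {",
    paste0(spec$state_names, " <- x[[", seq_len(ns), "]]"),
    "with(as.list(p), {",
    if (length(spec$aux)) paste0(names(spec$aux), " <- ", unname(spec$aux)),
    paste0("c(", paste(unname(spec$rhs_text), collapse = ",\n"), ")"),
    "})",
    "}")
  f <- eval(parse(text = paste(lines, collapse = "\n")))
  environment(f) <- baseenv()
  f
}

#' Evaluate a model's auxiliary quantities at a state
#'
#' @param model A [model_spec()].
#' @param x Named or ordered state vector.
#' @param params Parameter set (defaults to the model's own).
#' @return Named numeric vector of auxiliary values (empty if none).
#' @export
model_aux <- function(model, x, params = model$params) {
  if (!length(model$aux)) return(numeric(0))
  env <- list2env(as.list(params))
  for (i in seq_along(model$state_names)) {
    assign(model$state_names[i], unname(x[[i]]), envir = env)
  }
  out <- numeric(length(model$aux))
  names(out) <- names(model$aux)
  for (nm in names(model$aux)) {
    val <- eval(parse(text = model$aux[[nm]])[[1]], env)
    assign(nm, val, envir = env)
    out[nm] <- val
  }
  out
}

#' Replace parameter values in a model
#'
#' Returns a fresh model with the supplied parameter values substituted; the
#' original model is untouched. Unknown names are an error.
#'
#' @param model A [model_spec()].
#' @param ... Named parameter values, or a single named numeric vector.
#' @return A new `model_spec`.
#' @export
set_params <- function(model, ...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) ||
      (length(dots) == 1L && is_named_numeric(dots[[1]]))) {
    overrides <- dots[[1]]
  } else {
    overrides <- unlist(dots)
  }
  model$params <- apply_perturbation(
    model$params, scenario("adhoc", overrides = as.list(overrides)))
  model
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$name, "\n", sep = "")
  cat("  states (", length(x$state_names), "): ",
      paste(x$state_names, collapse = ", "), "\n", sep = "")
  cat("  parameters: ", length(x$params),
      if (!is.null(x$input_param)) paste0("  [input: ", x$input_param, "]"),
      "\n", sep = "")
  if (length(x$conserved)) {
    cat("  conserved totals: ",
        paste(vapply(x$conserved, `[[`, "", "label"), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# Numeric state upper bounds under a parameter set (Inf where unbounded).
state_upper_bounds <- function(model, params = model$params) {
  ub <- rep(Inf, length(model$state_names))
  names(ub) <- model$state_names
  for (nm in names(model$upper)) {
    v <- model$upper[[nm]]
    ub[nm] <- if (is.character(v) && v %in% names(params)) {
      unname(params[[v]])
    } else {
      as.numeric(v)
    }
  }
  ub
}

# Weight matrix of the conservation laws (rows = laws), or NULL.
conservation_matrix <- function(model) {
  if (!length(model$conserved)) return(NULL)
  do.call(rbind, lapply(model$conserved, `[[`, "weights"))
}

# Numeric totals of the conservation laws under a given parameter set.
conservation_totals <- function(model, params = model$params) {
  vapply(model$conserved, function(cl) {
    if (is.character(cl$total)) unname(params[[cl$total]]) else cl$total
  }, numeric(1))
}
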