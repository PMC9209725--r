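#' Integrate a model forward in time
#'
#' Solves the model ODEs with a stiff-capable integrator (`deSolve::lsoda`).
#' An optional input step applies a discontinuous parameter change at a
#' stated time, the standard way stimulus onset (amyloid-beta exposure, DNA
#' damage) is simulated: the system is integrated to the step time, the
#' parameter is switched, and integration restarts from the interior state.
#'
#' @param model A [model_spec()].
#' @param init Named initial state (defaults to the model's `init`).
#' @param times Strictly increasing time grid (arbitrary units).
#' @param input_step Optional `list(time=, param=, value=)` describing a
#'   stepwise parameter change.
#' @param rtol,atol Relative/absolute integration tolerances.
#' @param check If `TRUE`, verify finiteness, positivity (no state below
#'   `-1e-9`) and conservation of the model's conserved totals.
#' @return A `trajectory` object: list with `time`, `states` (time x states
#'   matrix), `events`, `model_name`, `params`.
#' @examples
#' m <- model_spec("decay", "x", c(k = 1), c(x = "-k * x"), init = c(x = 1))
#' tr <- integrate_model(m, times = seq(0, 1, by = 0.1))
#' tail(tr$states[, "x"], 1)  # ~ exp(-1)
#' @export
integrate_model <- function(model, init = model$init,
                            times = seq(0, 5000, by = 5),
                            input_step = NULL, rtol = 1e-8, atol = 1e-10,
                            check = TRUE) {
  if (is.null(init)) stop_config("no initial condition supplied")
  init <- init[model$state_names]
  if (any(is.na(init))) stop_config("`init` must name every state")
  if (isTRUE(model$nonneg) && any(init < 0)) {
    stop_config("`init` must be non-negative")
  }
  if (!is.null(model$upper)) {
    # MM interconversion terms are only defined up to the cycle total;
    # project the start into the physical domain
    init <- pmin(init, state_upper_bounds(model))
  }
  if (any(diff(times) <= 0)) stop_config("`times` must be strictly increasing")

  rhs <- model$rhs_fun
  desolve_fun <- function(t, y, parms) {
    d <- rhs(y, parms, t)
    if (any(!is.finite(d))) {
      bad <- model$state_names[which(!is.finite(d))[1]]
      stop("integration failure: non-finite derivative for state '",
           bad, "'", call. = FALSE)
    }
    list(d)
  }

  run_leg <- function(y0, tt, parms) {
    out <- deSolve::lsoda(y = y0, times = tt, func = desolve_fun,
                          parms = parms, rtol = rtol, atol = atol,
                          maxsteps = 50000)
    if (attr(out, "istate")[1] < 0) {
      stop("integration failure in model '", model$name, "'", call. = FALSE)
    }
    out
  }

  events <- list()
  if (is.null(input_step)) {
    out <- run_leg(init, times, model$params)
  } else {
    stopifnot(all(c("time", "param", "value") %in% names(input_step)))
    if (!input_step$param %in% names(model$params)) {
      stop_config("input_step parameter '", input_step$param, "' unknown")
    }
    ts <- input_step$time
    if (ts <= times[1]) {          # step at/before start: plain run
      m2 <- model
      m2$params[input_step$param] <- input_step$value
      tr <- integrate_model(m2, init = init, times = times, rtol = rtol,
                            atol = atol, check = check)
      tr$events <- list(input_step)
      return(tr)
    }
    pre <- times[times <= ts]
    post <- times[times > ts]
    if (!length(pre) || pre[length(pre)] < ts) pre <- c(pre, ts)
    out1 <- run_leg(init, pre, model$params)
    y_mid <- out1[nrow(out1), -1]
    p2 <- model$params
    p2[input_step$param] <- input_step$value
    out2 <- run_leg(y_mid, c(ts, post), p2)
    # drop the duplicated step time and any padding point not in `times`
    out <- rbind(out1[out1[, 1] %in% times, , drop = FALSE],
                 out2[out2[, 1] %in% post, , drop = FALSE])
    events <- list(input_step)
  }

  states <- out[, -1, drop = FALSE]
  colnames(states) <- model$state_names
  if (check) {
    if (any(!is.finite(states))) {
      stop("integration failure: non-finite state values", call. = FALSE)
    }
    if (isTRUE(model$nonneg) && min(states) < -1e-9) {
      bad <- colnames(states)[which(states == min(states), arr.ind = TRUE)[1, 2]]
      stop("positivity violation: state '", bad, "' reached ",
           format(min(states)), call. = FALSE)
    }
  }
  traj <- structure(
    list(time = out[, 1], states = states, events = events,
         model_name = model$name, params = model$params),
    class = "trajectory")
  if (check && length(model$conserved)) {
    drift <- conservation_drift(traj, model)
    if (any(drift > 1e-6)) {
      warning("conserved total(s) drifted beyond 1e-6: ",
              paste(names(drift)[drift > 1e-6], collapse = ", "),
              call. = FALSE)
    }
  }
  traj
}

#' Relative drift of each conserved total along a trajectory
#'
#' @param traj A `trajectory`.
#' @param model The model that produced it.
#' @return Named numeric vector of max relative deviations from the expected
#'   totals (relative to `max(1, total)`).
#' @export
conservation_drift <- function(traj, model) {
  W <- conservation_matrix(model)
  if (is.null(W)) return(numeric(0))
  totals <- conservation_totals(model, traj$params)
  vals <- traj$states %*% t(W)
  drift <- vapply(seq_along(totals), function(i) {
    max(abs(vals[, i] - totals[i])) / max(1, abs(totals[i]))
  }, numeric(1))
  names(drift) <- vapply(model$conserved, `[[`, "", "label")
  drift
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$model_name, ": ", length(x$time), " time points, ",
      ncol(x$states), " states, t in [", x$time[1], ", ",
      x$time[length(x$time)], "]\n", sep = "")
  invisible(x)
}

#' Final state of a trajectory
#' @param traj A `trajectory`.
#' @return Named state vector at the last time point.
#' @export
final_state <- function(traj) {
  traj$states[nrow(traj$states), ]
}

#' Integrate to (numerical) steady state
#'
#' Runs the model for a settling horizon and polishes the end point with a
#' Newton solve, returning an [equilibrium] when the residual converges and
#' otherwise the settled state itself.
#'
#' @param model A [model_spec()].
#' @param init Initial state (default the model's).
#' @param t_end Settling horizon (default 5000 time units).
#' @param polish If `TRUE` (default) polish with Newton.
#' @return Named state vector.
#' @export
settle <- function(model, init = model$init, t_end = 5000, polish = TRUE) {
  tr <- integrate_model(model, init = init,
                        times = seq(0, t_end, length.out = 201), check = FALSE)
  x <- final_state(tr)
  if (isTRUE(model$nonneg)) x <- pmax(x, 0)
  if (polish) {
    eq <- newton_equilibrium(model, x)
    if (!is.null(eq)) x <- eq$state
  }
  x
}
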