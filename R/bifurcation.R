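# One- and two-parameter bifurcation analysis.
#
# Strategy: dense multistart equilibrium enumeration along a control
# parameter grid (warm-started from neighbouring grid points), saddle nodes
# refined by bisection on the equilibrium count, plus an adaptive
# branch-tracing routine used for fast threshold localization in the
# sensitivity scan. This replaces pseudo-arclength continuation and is easy
# to cross-check against direct simulation.

equilibria_at <- function(model, control, value, warm = list(),
                          n_random = 20, seed = 1, dedup_tol = 1e-6,
                          expect_stable = list()) {
  params <- model$params
  params[control] <- value
  starts <- c(warm, multistart_grid(model, params, n_random = n_random,
                                    seed = seed))
  eqs <- suppressWarnings(
    find_equilibria(model, params = params, starts = starts,
                    dedup_tol = dedup_tol))
  # A stable branch seen at the neighbouring control value must either still
  # be found or have genuinely folded. When Newton alone loses it, relax the
  # dynamics from the old state and polish: if the system still settles
  # nearby the branch persists; if it falls onto another attractor the
  # branch is gone (a fold).
  m <- model
  m$params <- params
  if (!isTRUE(model$nonneg)) {
    # unbounded (toy/analytic) models can diverge under relaxation; their
    # Newton problems are benign, so skip the dynamic fallback
    expect_stable <- list()
  } else if (!length(eqs) && !is.null(model$init)) {
    expect_stable <- c(expect_stable, list(model$init))
  }
  for (ps in expect_stable) {
    ps <- unname(ps)
    matched <- any(vapply(eqs, function(e) {
      max_norm(e$state, ps) < 0.15 * (1 + max(abs(ps)))
    }, TRUE))
    if (matched) next
    relax <- tryCatch(
      settle(m, init = stats::setNames(ps, model$state_names),
             t_end = 2500, polish = FALSE),
      error = function(e) NULL)
    if (is.null(relax)) next
    sol <- newton_equilibrium(model, relax, params)
    if (is.null(sol)) next
    dup <- any(vapply(eqs, function(e) {
      max_norm(e$state, sol$state) < 1e-4 * (1 + max(abs(sol$state)))
    }, TRUE))
    if (!dup) {
      eqs <- c(eqs, list(new_equilibrium(model, sol, params)))
    }
  }
  eqs
}

warm_starts <- function(eqs) lapply(eqs, function(e) unname(e$state))

#' One-parameter bifurcation sweep
#'
#' Enumerates the equilibria of a model over a grid of control-parameter
#' values, locates saddle-node (fold) bifurcations by bisection on the
#' equilibrium count, and reports the bistable interval(s). For the fold-pair
#' topologies arising here, each bistable interval carries exactly three
#' equilibria (two stable, one unstable) and each boundary interior to the
#' scanned range is a saddle node.
#'
#' Saddle nodes are labelled per bistable interval, ordered by control value:
#' the upper edge of the first interval is `SN1` (the activation threshold),
#' its lower edge `SN2` (the deactivation threshold); a second interval gets
#' `SN4` (lower) and `SN3` (upper), matching the usual numbering for a
#' two-switch system. A lower edge that coincides with the start of the scan
#' range is not a fold: the corresponding deactivation threshold is reported
#' as absent, which for a range starting at zero operationalizes an
#' irreversible switch on a physically non-negative input.
#'
#' @param model A [model_spec()].
#' @param control Parameter name to sweep (defaults to the model's input).
#' @param range Length-2 numeric `(lo, hi)`, `lo < hi`.
#' @param n_points Number of grid points (>= 50).
#' @param refine_tol Bracketing width for fold refinement
#'   (default `(hi - lo) / 1e4`).
#' @param n_random Latin-hypercube starts per full multistart enumeration.
#' @param full_every Run a full multistart every this many grid points
#'   (intermediate points are warm-started from their neighbour).
#' @param seed Seed for the random starts.
#' @return A `bifurcation_diagram`: list with `control`, `values`,
#'   `equilibria` (per-value list of `equilibrium`), `n_total`, `n_stable`,
#'   `saddle_nodes` (data frame: label, value, width, plus a list column of
#'   fold states), `bistable_intervals`, `bistable_interval` (the first, or
#'   `NULL`), `incomplete` (control values with no equilibrium found).
#' @examples
#' m <- model_spec("fold", "x", c(mu = 0), c(x = "mu - x^2"),
#'                 init = c(x = 1), input_param = "mu")
#' bd <- sweep_bifurcation(m, range = c(-1, 1), n_points = 51)
#' bd$saddle_nodes$value  # ~ 0
#' @export
sweep_bifurcation <- function(model, control = model$input_param, range,
                              n_points = 81,
                              refine_tol = diff(range) / 1e4,
                              n_random = 20, full_every = 10, seed = 1) {
  stopifnot(length(range) == 2, range[1] < range[2])
  if (n_points < 50) stop_config("n_points must be >= 50")
  if (is.null(control)) stop_config("no control parameter given")
  values <- seq(range[1], range[2], length.out = n_points)

  anchor_starts <- c(lapply(model$anchors, function(a) {
    unname(a[model$state_names])
  }), if (!is.null(model$init)) list(unname(model$init)))

  stable_states <- function(eqs) {
    lapply(Filter(function(e) e$stable, eqs), function(e) unname(e$state))
  }

  # two passes: ascending and descending the control axis, so that a branch
  # born anywhere inside the range is picked up at its monostable end and
  # followed (with the relax fallback) through the whole window it spans
  eq_list <- vector("list", n_points)
  for (direction in list(seq_len(n_points), rev(seq_len(n_points)))) {
    prev <- list()
    prev_stable <- list()
    for (i in direction) {
      full <- (i - 1L) %% full_every == 0L || !length(prev)
      found <- equilibria_at(
        model, control, values[i],
        warm = c(prev, warm_starts(eq_list[[i]]), anchor_starts),
        n_random = if (full) n_random else 2, seed = seed,
        expect_stable = c(prev_stable, stable_states(eq_list[[i]])))
      # merge with the other pass
      for (e in found) {
        dup <- any(vapply(eq_list[[i]], function(k) {
          max_norm(k$state, e$state) < 1e-5 * (1 + max(abs(e$state)))
        }, TRUE))
        if (!dup) eq_list[[i]] <- c(eq_list[[i]], list(e))
      }
      if (length(found)) {
        prev <- warm_starts(found)
        prev_stable <- stable_states(found)
      }
    }
  }
  n_total <- vapply(eq_list, length, integer(1))
  n_stable <- vapply(eq_list, function(e) sum(vapply(e, `[[`, TRUE, "stable")),
                     integer(1))
  incomplete <- values[n_total == 0]

  count_at <- function(v, warm, expect) {
    eqs <- equilibria_at(model, control, v, warm = c(warm, anchor_starts),
                         n_random = 4, seed = seed, expect_stable = expect)
    list(n = sum(vapply(eqs, `[[`, TRUE, "stable")), eqs = eqs)
  }

  # refine each grid interval over which the stable-attractor count changes
  # (stable states are recoverable by relaxation, so their count is the
  # robust signature of a fold)
  folds <- list()
  for (i in which(diff(n_stable) != 0)) {
    lo <- values[i]; hi <- values[i + 1]
    n_lo <- n_stable[i]; n_hi <- n_stable[i + 1]
    warm <- c(warm_starts(eq_list[[i]]), warm_starts(eq_list[[i + 1]]))
    many_side <- if (n_lo > n_hi) eq_list[[i]] else eq_list[[i + 1]]
    expect <- c(stable_states(eq_list[[i]]), stable_states(eq_list[[i + 1]]))
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      cm <- count_at(mid, warm, expect)
      if (cm$n == n_lo) lo <- mid else hi <- mid
      if (cm$n > 0) {
        warm <- c(warm_starts(cm$eqs), warm)
        expect <- stable_states(cm$eqs)
        if (cm$n == max(n_lo, n_hi)) many_side <- cm$eqs
      }
    }
    folds <- c(folds, list(list(
      value = (lo + hi) / 2, width = hi - lo,
      side = if (n_lo > n_hi) "upper" else "lower",
      state = fold_state(many_side))))
  }

  # bistable intervals from the grid counts + refined fold locations
  sn <- label_folds(folds, values, n_stable, range)

  structure(list(control = control, values = values, equilibria = eq_list,
                 n_total = n_total, n_stable = n_stable,
                 saddle_nodes = sn$table,
                 bistable_intervals = sn$intervals,
                 bistable_interval = if (length(sn$intervals)) sn$intervals[[1]],
                 incomplete = incomplete, range = range),
            class = "bifurcation_diagram")
}

# state at a fold ~ midpoint of the two closest equilibria on the many-side
fold_state <- function(eqs) {
  if (length(eqs) < 2) {
    return(if (length(eqs)) eqs[[1]]$state else NULL)
  }
  best <- c(1, 2); bd <- Inf
  for (a in seq_along(eqs)) for (b in seq_along(eqs)) {
    if (a < b) {
      d <- max_norm(eqs[[a]]$state, eqs[[b]]$state)
      if (d < bd) { bd <- d; best <- c(a, b) }
    }
  }
  (eqs[[best[1]]]$state + eqs[[best[2]]]$state) / 2
}

label_folds <- function(folds, values, n_stable, range) {
  if (length(folds)) {
    ord <- order(vapply(folds, `[[`, 0, "value"))
    folds <- folds[ord]
  }
  # walk the control axis: a region with >= 2 stable attractors is bistable
  intervals <- list()
  open_lo <- if (n_stable[1] >= 2) range[1] else NA_real_
  open_lo_fold <- NA_integer_
  labels <- character(length(folds))
  for (k in seq_along(folds)) {
    f <- folds[[k]]
    if (f$side == "lower") {          # count increases upward: interval opens
      open_lo <- f$value; open_lo_fold <- k
    } else {                          # interval closes at this fold
      if (!is.na(open_lo)) {
        i <- length(intervals) + 1L
        intervals[[i]] <- c(open_lo, f$value)
        labels[k] <- paste0("SN", 2 * i - 1)                 # upper edge
        if (!is.na(open_lo_fold)) labels[open_lo_fold] <- paste0("SN", 2 * i)
        open_lo <- NA_real_; open_lo_fold <- NA_integer_
      } else {
        labels[k] <- "SN?"
      }
    }
  }
  if (!is.na(open_lo)) {              # bistable up to the end of the range
    i <- length(intervals) + 1L
    intervals[[i]] <- c(open_lo, range[2])
    if (!is.na(open_lo_fold)) labels[open_lo_fold] <- paste0("SN", 2 * i)
  }
  tab <- data.frame(label = labels,
                    value = vapply(folds, `[[`, 0, "value"),
                    width = vapply(folds, `[[`, 0, "width"),
                    side = vapply(folds, `[[`, "", "side"),
                    stringsAsFactors = FALSE)
  tab$state <- lapply(folds, `[[`, "state")
  list(table = tab, intervals = intervals)
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat("<bifurcation_diagram> control = ", x$control, " in [",
      x$range[1], ", ", x$range[2], "]\n", sep = "")
  if (nrow(x$saddle_nodes)) {
    for (i in seq_len(nrow(x$saddle_nodes))) {
      cat(sprintf("  %-4s at %s = %.6g (+/- %.2g)\n",
                  x$saddle_nodes$label[i], x$control,
                  x$saddle_nodes$value[i], x$saddle_nodes$width[i] / 2))
    }
  } else cat("  no saddle nodes in range\n")
  for (iv in x$bistable_intervals) {
    cat(sprintf("  bistable on [%.6g, %.6g]\n", iv[1], iv[2]))
  }
  if (length(x$incomplete)) {
    cat("  INCOMPLETE at", length(x$incomplete), "control values\n")
  }
  invisible(x)
}

#' Look up a labelled saddle node in a diagram
#'
#' @param diagram A `bifurcation_diagram`.
#' @param label Saddle-node label (e.g. `"SN1"`).
#' @return The control-parameter value of the fold, or `NA` if absent.
#' @export
diagram_fold <- function(diagram, label) {
  i <- match(label, diagram$saddle_nodes$label)
  if (is.na(i)) NA_real_ else diagram$saddle_nodes$value[i]
}

#' Is a swept switch irreversible?
#'
#' A bistable switch is irreversible when its activation fold (`SN1`) lies in
#' the scanned range but the deactivation fold (`SN2`) does not, i.e. the
#' high branch persists all the way down to the start of the range. Scanning
#' from zero, this means no non-negative input value can switch the system
#' back.
#'
#' @param diagram A `bifurcation_diagram`.
#' @return `TRUE`/`FALSE`.
#' @export
is_irreversible <- function(diagram) {
  sn1 <- diagram_fold(diagram, "SN1")
  sn2 <- diagram_fold(diagram, "SN2")
  !is.na(sn1) && is.na(sn2) && length(diagram$bistable_intervals) >= 1 &&
    abs(diagram$bistable_intervals[[1]][1] - diagram$range[1]) < 1e-12
}

#' Extract a plotted-variable branch table from a diagram
#'
#' @param diagram A `bifurcation_diagram`.
#' @param state State variable name.
#' @return Data frame with columns `control`, `value`, `stable`.
#' @export
diagram_branches <- function(diagram, state) {
  rows <- do.call(rbind, lapply(seq_along(diagram$values), function(i) {
    eqs <- diagram$equilibria[[i]]
    if (!length(eqs)) return(NULL)
    data.frame(control = diagram$values[i],
               value = vapply(eqs, function(e) e$state[[state]], numeric(1)),
               stable = vapply(eqs, `[[`, TRUE, "stable"))
  }))
  rows
}

# ---------------------------------------------------------------------------
# Branch tracing: fast fold localization used by the sensitivity scan.

# Follow the equilibrium branch through `x0` from control value `from`
# toward `to`; stop at a fold (branch lost) or at `to`.
trace_branch <- function(model, control, from, to, x0,
                         params = model$params, n_steps = 40,
                         jump_tol = 0.25, width_tol = abs(to - from) / 1e4) {
  p <- params
  p[control] <- from
  sol <- newton_equilibrium(model, x0, p)
  if (is.null(sol)) stop_config("trace_branch: no equilibrium at start")
  x <- sol$state
  v <- from
  dir <- sign(to - from)
  step0 <- (to - from) / n_steps
  step <- step0
  repeat {
    if (dir * (v - to) >= -1e-15) {
      return(list(fold = NA_real_, state = x, reached_end = TRUE,
                  end_state = x))
    }
    vn <- if (dir * (v + step - to) > 0) to else v + step
    p[control] <- vn
    sol <- newton_equilibrium(model, x, p)
    ok <- !is.null(sol) &&
      max_norm(sol$state, x) <= jump_tol * (1 + max(abs(x))) &&
      leading_eigenvalue(model, sol$state, p) < 0
    if (ok) {
      v <- vn; x <- sol$state
      step <- dir * min(abs(step) * 1.6, abs(step0))
    } else {
      if (abs(step) <= width_tol) {
        return(list(fold = v + step / 2, state = x, reached_end = FALSE,
                    end_state = x, width = abs(step)))
      }
      step <- step / 2
    }
  }
}

#' Locate the activation threshold (fold) along a stable branch
#'
#' Settles the model on the branch through `init` at `range[1]` and follows
#' that branch toward `range[2]`, returning the control value at which the
#' branch is lost (the saddle node) or `NA` when the branch persists across
#' the whole range.
#'
#' @param model A [model_spec()].
#' @param control Control parameter (default the model input).
#' @param range Scan range `(lo, hi)`; the branch is followed from `lo`.
#' @param init State from which the starting branch is settled.
#' @param params Optional parameter override set.
#' @param predicate Optional function of the settled post-fold state. When
#'   given, the threshold reported is the fold whose downhill relaxation
#'   satisfies the predicate (e.g. "is the state pathological?"); folds onto
#'   intermediate branches that do not satisfy it are traced through. This
#'   separates a small secondary fold from the main switching threshold in
#'   models with more than one subswitch.
#' @param ... Passed to `trace_branch` (`n_steps`, `jump_tol`, `width_tol`).
#' @return List with `threshold` (control value or `NA`), `state` (last
#'   branch state before the fold), `post_state` (the settled state just
#'   past the reported fold, when a predicate is used) and `reached_end`.
#' @export
find_threshold <- function(model, control = model$input_param, range,
                           init = model$init, params = model$params,
                           predicate = NULL, ...) {
  m <- model
  m$params <- params
  m$params[control] <- range[1]
  x0 <- settle(m, init = init)
  trace_to_threshold(m, control, range, x0, params = m$params,
                     predicate = predicate, ...)
}

# trace the branch through intermediate folds until the relaxed post-fold
# state satisfies `predicate` (or the first fold, when predicate is NULL)
trace_to_threshold <- function(model, control, range, x0,
                               params = model$params, predicate = NULL,
                               ...) {
  m <- model
  m$params <- params
  from <- range[1]
  for (leg in 1:6) {
    tr <- trace_branch(m, control, from, range[2], x0, params = m$params,
                       ...)
    if (tr$reached_end) {
      return(list(threshold = NA_real_, state = tr$state,
                  post_state = NULL, reached_end = TRUE))
    }
    if (is.null(predicate)) {
      return(list(threshold = tr$fold, state = tr$state, post_state = NULL,
                  reached_end = FALSE))
    }
    # relax just past the fold and ask the predicate where we landed
    step_past <- max(diff(range) / 200, 2 * (tr$width %||% 0))
    m2 <- m
    m2$params[control] <- min(tr$fold + step_past, range[2])
    landed <- settle(m2, init = tr$state)
    if (isTRUE(predicate(landed))) {
      return(list(threshold = tr$fold, state = tr$state,
                  post_state = landed, reached_end = FALSE))
    }
    from <- m2$params[[control]]
    x0 <- landed
  }
  list(threshold = NA_real_, state = x0, post_state = NULL,
       reached_end = FALSE)
}

#' Two-parameter saddle-node loci and cusp detection
#'
#' Repeats a one-parameter sweep of `control` for each value of a second
#' parameter and records how the fold pair moves. A cusp is recorded between
#' consecutive second-parameter values where the fold pair is lost (the two
#' saddle nodes collide and disappear).
#'
#' @param model A [model_spec()].
#' @param control Primary (swept) parameter name.
#' @param range Sweep range for `control`.
#' @param second Second parameter name.
#' @param second_values Non-negative values of the second parameter.
#' @param ... Passed to [sweep_bifurcation()].
#' @return A `two_param_loci` object: data frame `loci` (second value, SN1,
#'   SN2, n_folds), list `diagrams`, and `cusp_points` (second-parameter
#'   values bracketing each loss of the fold pair, as midpoints).
#' @export
two_parameter_scan <- function(model, control, range, second, second_values,
                               ...) {
  if (any(second_values < 0)) stop_config("second_values must be >= 0")
  diagrams <- vector("list", length(second_values))
  loci <- data.frame(second = second_values, sn1 = NA_real_, sn2 = NA_real_,
                     n_folds = 0L)
  for (i in seq_along(second_values)) {
    m <- set_params(model, stats::setNames(second_values[i], second))
    bd <- sweep_bifurcation(m, control = control, range = range, ...)
    diagrams[[i]] <- bd
    loci$sn1[i] <- diagram_fold(bd, "SN1")
    loci$sn2[i] <- diagram_fold(bd, "SN2")
    loci$n_folds[i] <- nrow(bd$saddle_nodes)
  }
  has_pair <- !is.na(loci$sn1)
  cusp <- numeric(0)
  for (i in seq_len(length(second_values) - 1)) {
    if (has_pair[i] != has_pair[i + 1]) {
      cusp <- c(cusp, mean(second_values[i:(i + 1)]))
    }
  }
  structure(list(control = control, second = second, loci = loci,
                 diagrams = diagrams, cusp_points = cusp),
            class = "two_param_loci")
}

#' @export
print.two_param_loci <- function(x, ...) {
  cat("<two_param_loci> ", x$control, " folds vs ", x$second, "\n", sep = "")
  print(x$loci, row.names = FALSE)
  if (length(x$cusp_points)) {
    cat("  cusp near ", x$second, " = ",
        paste(format(x$cusp_points, digits = 4), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
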