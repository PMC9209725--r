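# Equilibrium location, stability, multistart enumeration.
#
# Conserved linear combinations make the raw Jacobian exactly singular, so
# Newton iterations replace one derivative equation per conservation law with
# the algebraic constraint w.x = total, and stability is judged from the
# Jacobian projected onto the orthogonal complement of the conserved
# directions.

# Central finite-difference Jacobian of the RHS, step 1e-6 * max(1, |x|).
fd_jacobian <- function(model, x, params = model$params) {
  n <- length(x)
  J <- matrix(0, n, n)
  f <- model$rhs_fun
  for (j in seq_len(n)) {
    h <- 1e-6 * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp, params) - f(xm, params)) / (2 * h)
  }
  J
}

# Orthonormal basis of the complement of the conserved directions.
conservation_complement <- function(W) {
  qr.Q(qr(t(W)), complete = TRUE)[, -seq_len(nrow(W)), drop = FALSE]
}

# Damped Newton solve for rhs(x) = 0. Conservation laws make the raw
# Jacobian singular, so the iteration runs in the affine subspace
# {x : W x = totals}: the start is projected onto it and steps are taken
# along an orthonormal basis of its tangent space.
# Returns list(state, residual) or NULL when not converged.
newton_equilibrium <- function(model, x0, params = model$params,
                               tol = 1e-9, maxit = 60) {
  x <- if (!is.null(names(x0))) as.numeric(x0[model$state_names]) else as.numeric(x0)
  if (length(x) != length(model$state_names) || any(is.na(x))) {
    x <- as.numeric(x0)
  }
  x <- unname(x)
  if (isTRUE(model$nonneg)) x <- pmax(x, 0)
  if (!is.null(model$upper)) {
    x <- pmin(x, unname(state_upper_bounds(model, params)))
  }
  W <- conservation_matrix(model)
  N <- NULL
  if (!is.null(W)) {
    totals <- conservation_totals(model, params)
    # project the start onto the constraint manifold
    corr <- tryCatch(
      t(W) %*% solve(W %*% t(W), as.numeric(W %*% x) - totals),
      error = function(e) NULL)
    if (is.null(corr)) return(NULL)
    x <- x - as.numeric(corr)
    N <- conservation_complement(W)
  }

  Fred <- function(x) {
    r <- model$rhs_fun(x, params)
    if (is.null(N)) r else as.numeric(crossprod(N, r))
  }
  r <- Fred(x)
  if (any(!is.finite(r))) return(NULL)
  for (it in seq_len(maxit)) {
    if (max(abs(r)) < tol) break
    J <- fd_jacobian(model, x, params)
    if (!is.null(N)) J <- crossprod(N, J %*% N)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    if (!is.null(N)) step <- as.numeric(N %*% step)
    lam <- 1
    repeat {
      xn <- x + lam * step
      rn <- Fred(xn)
      if (all(is.finite(rn)) &&
          (max(abs(rn)) < max(abs(r)) || lam < 1e-4)) break
      lam <- lam / 2
    }
    if (any(!is.finite(rn))) return(NULL)
    x <- xn; r <- rn
  }
  if (max(abs(r)) >= tol) return(NULL)
  if (isTRUE(model$nonneg)) {
    if (min(x) < -1e-8) return(NULL)     # nonphysical equilibrium
    x <- pmax(x, 0)
  }
  if (!is.null(model$upper)) {
    ub <- state_upper_bounds(model, params)
    if (any(x > ub + 1e-8)) return(NULL) # beyond the rate law's domain
  }
  names(x) <- model$state_names
  list(state = x, residual = max(abs(model$rhs_fun(unname(x), params))))
}

# Leading eigenvalue real part on the dynamically relevant subspace.
leading_eigenvalue <- function(model, x, params = model$params) {
  J <- fd_jacobian(model, x, params)
  W <- conservation_matrix(model)
  if (!is.null(W)) {
    N <- conservation_complement(W)
    J <- crossprod(N, J %*% N)
  }
  max(Re(eigen(J, only.values = TRUE)$values))
}

new_equilibrium <- function(model, sol, params = model$params) {
  lead <- leading_eigenvalue(model, sol$state, params)
  structure(list(state = sol$state, residual = sol$residual,
                 stable = lead < 0, leading_re = lead),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat("<equilibrium> ", if (x$stable) "stable" else "unstable",
      " (leading Re = ", format(x$leading_re, digits = 3),
      ", residual = ", format(x$residual, digits = 3), ")\n", sep = "")
  print(round(x$state, 5))
  invisible(x)
}

# Default multistart grid: uniform levels per state, model anchors, and a
# seeded Latin hypercube over [0, 2] per state (projected onto conserved
# totals where applicable).
multistart_grid <- function(model, params = model$params, n_random = 30,
                            seed = 1, levels = NULL) {
  if (is.null(levels)) {
    levels <- c(0, 0.1, 0.5, 1, 2)
    if (!isTRUE(model$nonneg)) levels <- c(levels, -0.5, -1, -2)
  }
  n <- length(model$state_names)
  starts <- lapply(levels, function(v) rep(v, n))
  for (a in model$anchors) starts <- c(starts, list(unname(a[model$state_names])))
  if (!is.null(model$init)) starts <- c(starts, list(unname(model$init)))
  if (n_random > 0) {
    H <- with_preserved_seed(seed, lhs::randomLHS(n_random, n)) * 2
    starts <- c(starts, lapply(seq_len(n_random), function(i) H[i, ]))
  }
  W <- conservation_matrix(model)
  if (!is.null(W)) {
    totals <- conservation_totals(model, params)
    starts <- lapply(starts, function(s) {
      # rescale participating states so each conserved total is honoured
      for (i in seq_len(nrow(W))) {
        idx <- which(W[i, ] != 0)
        cur <- sum(W[i, idx] * s[idx])
        if (cur > 0) {
          s[idx] <- s[idx] * totals[i] / cur
        } else if (totals[i] > 0) {
          s[idx[1]] <- totals[i] / W[i, idx[1]]
        }
      }
      s
    })
  }
  starts
}

#' Enumerate equilibria by multistart Newton iteration
#'
#' Runs a damped Newton solve from every starting point and merges the
#' convergent solutions, deduplicating in max-norm. Stability is assessed
#' from finite-difference Jacobian eigenvalues (projected off the conserved
#' directions when the model has conservation laws).
#'
#' @param model A [model_spec()].
#' @param params Parameter set (defaults to the model's).
#' @param starts Optional list of start vectors; when `NULL` a default grid
#'   of uniform levels, model anchors and seeded Latin-hypercube points is
#'   used.
#' @param n_random Number of Latin-hypercube starts in the default grid.
#' @param seed Seed for the random starts (RNG state is restored).
#' @param tol Residual max-norm tolerance for acceptance.
#' @param dedup_tol Max-norm radius within which solutions are merged.
#' @return List of `equilibrium` objects (possibly empty, with a warning when
#'   no start converged), sorted by the first state variable.
#' @examples
#' m <- model_spec("fold", "x", c(mu = 1), c(x = "mu - x^2"),
#'                 init = c(x = 1))
#' eqs <- find_equilibria(m, starts = list(2, -2))
#' vapply(eqs, function(e) e$state, numeric(1))
#' @export
find_equilibria <- function(model, params = model$params, starts = NULL,
                            n_random = 30, seed = 1, tol = 1e-9,
                            dedup_tol = 1e-6) {
  if (is.null(starts)) {
    starts <- multistart_grid(model, params, n_random = n_random, seed = seed)
  }
  if (!length(starts)) stop_config("empty multistart grid")
  sols <- list()
  for (s in starts) {
    sol <- newton_equilibrium(model, s, params, tol = tol)
    if (is.null(sol)) next
    dup <- FALSE
    for (kept in sols) {
      if (max_norm(kept$state, sol$state) < dedup_tol) { dup <- TRUE; break }
    }
    if (!dup) sols <- c(sols, list(sol))
  }
  if (!length(sols)) {
    warning("no Newton start converged for model '", model$name, "'",
            call. = FALSE)
    return(list())
  }
  eqs <- lapply(sols, new_equilibrium, model = model, params = params)
  ord <- order(vapply(eqs, function(e) e$state[[1]], numeric(1)))
  eqs[ord]
}
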