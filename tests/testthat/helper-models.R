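# Toy models with closed-form equilibria and folds, used as oracles.

toy_decay <- function(k = 1) {
  model_spec("decay", "x", c(k = k), c(x = "-k * x"), init = c(x = 1))
}

# dx/dt = mu - x^2: fold at mu = 0, equilibria at +/- sqrt(mu)
toy_fold <- function(mu = 1) {
  model_spec("fold", "x", c(mu = mu), c(x = "mu - x^2"),
             init = c(x = 1), input_param = "mu")
}

# dx/dt = mu + x - cc * x^3: folds at mu = -/+ 2 / (3 * sqrt(3 * cc))
toy_cubic <- function(mu = -1, cc = 1, extra = NULL) {
  p <- c(mu = mu, cc = cc)
  if (!is.null(extra)) p <- c(p, extra)
  model_spec("cubic", "x", p, c(x = "mu + x - cc * x^3"),
             init = c(x = 0), input_param = "mu")
}

cubic_fold_mu <- function(cc = 1) 2 / (3 * sqrt(3 * cc))

# reversible binding A + B <-> C with conserved totals A+C and B+C
toy_binding <- function(ka = 10, kd = 1, a0 = 1, b0 = 0.6) {
  model_spec(
    "binding", c("A", "B", "C"), c(ka = ka, kd = kd, A_T = a0, B_T = b0),
    c(A = "-ka * A * B + kd * C",
      B = "-ka * A * B + kd * C",
      C = "ka * A * B - kd * C"),
    conserved = list(
      list(label = "A_total", weights = c(A = 1, C = 1), total = "A_T"),
      list(label = "B_total", weights = c(B = 1, C = 1), total = "B_T")),
    init = c(A = a0, B = b0, C = 0), nonneg = TRUE)
}

expect_state_close <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(a - b)), tol)
}
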