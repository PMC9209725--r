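test_that("integration matches the closed form for exponential decay", {
  m <- toy_decay()
  tr <- integrate_model(m, times = seq(0, 1, by = 0.01))
  expect_equal(unname(final_state(tr)[["x"]]), exp(-1), tolerance = 1e-7)
})

test_that("an input step switches the parameter at the stated time", {
  m <- toy_decay(k = 1)
  tr <- integrate_model(m, times = seq(0, 2, by = 0.01),
                        input_step = list(time = 1, param = "k", value = 3))
  # x(2) = exp(-1) * exp(-3): decay at rate 1 then rate 3
  expect_equal(unname(final_state(tr)[["x"]]), exp(-1) * exp(-3),
               tolerance = 1e-6)
  expect_length(tr$events, 1)
  # step at t <= start behaves as a plain run with the new value
  tr0 <- integrate_model(m, times = seq(0, 1, by = 0.01),
                         input_step = list(time = 0, param = "k", value = 2))
  expect_equal(unname(final_state(tr0)[["x"]]), exp(-2), tolerance = 1e-6)
})

test_that("invalid grids and missing states are rejected", {
  m <- toy_decay()
  expect_error(integrate_model(m, times = c(0, 1, 1)), "increasing")
  expect_error(integrate_model(m, init = c(y = 1)), "every state")
})

test_that("positivity violations are reported for concentration models", {
  sink_model <- model_spec("sink", "x", c(k = 1), c(x = "-k"),
                           init = c(x = 0.01), nonneg = TRUE)
  expect_error(
    integrate_model(sink_model, times = seq(0, 1, by = 0.1)),
    "positivity violation.*x")
})

test_that("non-finite derivatives name the offending state", {
  m <- model_spec("nanny", "x", c(k = 1), c(x = "sqrt(x - 1) * k"),
                  init = c(x = 0))
  expect_error(
    suppressWarnings(integrate_model(m, times = seq(0, 1, by = 0.1))),
    "non-finite derivative.*x")
})

test_that("conserved totals drift less than 1e-6 along trajectories", {
  b <- toy_binding()
  tr <- integrate_model(b, times = seq(0, 50, by = 0.5))
  expect_lt(max(conservation_drift(tr, b)), 1e-6)

  m1 <- build_module1()
  tr1 <- integrate_model(m1, times = seq(0, 2000, by = 20),
                         input_step = list(time = 500, param = "Abeta",
                                           value = 0.05))
  expect_lt(max(conservation_drift(tr1, m1)), 1e-6)
})
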