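test_that("model construction validates its inputs", {
  expect_error(
    model_spec("bad", "x", c(k = 1), c(x = "-k * y")),
    "unresolved symbols.*y")
  expect_error(
    model_spec("bad", c("x", "y"), c(k = 1), c(x = "-k * x")),
    "one expression per state")
  expect_error(
    model_spec("bad", "x", c(k = -1), c(x = "-k * x"), nonneg = TRUE),
    "non-negative")
  expect_error(
    model_spec("bad", "x", c(k = Inf), c(x = "-k * x")),
    "finite")
  expect_error(
    model_spec("bad", "x", c(k = 1), c(x = "-k * x"), init = c(z = 1)),
    "init")
  expect_error(
    model_spec("bad", "x", c(k = 1), c(x = "-k * x"), input_param = "nope"),
    "not a parameter")
})

test_that("the compiled RHS evaluates the stated expressions", {
  m <- toy_cubic(mu = 0.3, cc = 2)
  x <- 0.7
  expect_equal(m$rhs_fun(x, m$params), 0.3 + x - 2 * x^3)

  b <- toy_binding()
  d <- b$rhs_fun(c(0.5, 0.3, 0.1), b$params)
  flux <- -10 * 0.5 * 0.3 + 1 * 0.1
  expect_equal(d, c(flux, flux, -flux))
})

test_that("auxiliary quantities are evaluated in order", {
  m <- model_spec("aux", "x", c(a = 2),
                  c(x = "-g * x"),
                  aux = c(h = "a + 1", g = "h * 2"))
  expect_equal(model_aux(m, c(x = 1)), c(h = 3, g = 6))
  expect_equal(m$rhs_fun(1, m$params), -6)
})

test_that("conservation helpers expose weights and totals", {
  b <- toy_binding(a0 = 2, b0 = 1.5)
  W <- neurocycle:::conservation_matrix(b)
  expect_equal(dim(W), c(2, 3))
  expect_equal(neurocycle:::conservation_totals(b), c(2, 1.5))
})
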