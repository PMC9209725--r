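test_that("a linear sink has exactly one stable equilibrium at the origin", {
  eqs <- find_equilibria(toy_decay(), starts = list(2, -1, 0.3))
  expect_length(eqs, 1)
  expect_equal(unname(eqs[[1]]$state[["x"]]), 0, tolerance = 1e-9)
  expect_true(eqs[[1]]$stable)
})

test_that("the fold normal form has one stable and one unstable equilibrium", {
  eqs <- find_equilibria(toy_fold(mu = 1), starts = list(2, -2, 0.5, -0.5))
  expect_length(eqs, 2)
  states <- vapply(eqs, function(e) e$state[["x"]], numeric(1))
  stable <- vapply(eqs, `[[`, TRUE, "stable")
  expect_equal(sort(states), c(-1, 1), tolerance = 1e-8)
  expect_equal(stable[order(states)], c(FALSE, TRUE))
  # stability flag is consistent with the leading eigenvalue sign
  for (e in eqs) expect_equal(e$stable, e$leading_re < 0)
})

test_that("duplicate solutions are merged within the dedup radius", {
  eqs <- find_equilibria(toy_decay(),
                         starts = list(1, 1 + 1e-9, 0.5, 2, -3))
  expect_length(eqs, 1)
})

test_that("no convergent start gives an empty list with a warning", {
  m <- model_spec("drift", "x", c(k = 1), c(x = "k"), init = c(x = 0))
  expect_warning(eqs <- find_equilibria(m, starts = list(0, 1)),
                 "no Newton start converged")
  expect_length(eqs, 0)
})

test_that("conserved systems converge to the constrained equilibrium", {
  b <- toy_binding(ka = 10, kd = 1, a0 = 1, b0 = 0.6)
  eqs <- find_equilibria(b, n_random = 10, seed = 1)
  expect_length(eqs, 1)
  st <- eqs[[1]]$state
  # mass balance and detailed balance at equilibrium
  expect_equal(unname(st[["A"]] + st[["C"]]), 1, tolerance = 1e-8)
  expect_equal(unname(st[["B"]] + st[["C"]]), 0.6, tolerance = 1e-8)
  expect_equal(unname(10 * st[["A"]] * st[["B"]]), unname(st[["C"]]),
               tolerance = 1e-6)
  expect_true(eqs[[1]]$stable)
})

test_that("stable equilibria attract a 1% perturbation; saddles do not", {
  # stable node of the cubic at mu = 0: x = 1 (plus saddle at 0)
  m <- toy_cubic(mu = 0, cc = 1)
  eqs <- find_equilibria(m, starts = list(2, 0.01, -2))
  for (e in eqs) {
    x0 <- e$state + 0.01 * (abs(e$state) + 0.1)
    xf <- final_state(integrate_model(m, init = x0,
                                      times = seq(0, 200, by = 1)))
    returned <- max(abs(xf - e$state)) < 1e-4 * (1 + max(abs(e$state)))
    expect_equal(returned, e$stable)
  }
})

test_that("nonphysical equilibria beyond a state bound are rejected", {
  # the MM activation term continues analytically past x = total; the
  # bound marks that continuation as outside the model's domain
  m <- model_spec("mm", "x", c(a = 2, i = 0.5, TT = 1, J = 0.05),
                  c(x = "a * (TT - x) / (J + TT - x) - i * x / (J + x)"),
                  init = c(x = 0), nonneg = TRUE, upper = c(x = "TT"))
  eqs <- find_equilibria(m, n_random = 20, seed = 2)
  for (e in eqs) expect_lte(e$state[["x"]], 1 + 1e-8)
})
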