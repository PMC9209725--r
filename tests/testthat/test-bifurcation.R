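test_that("the sweep localizes the fold of dx/dt = mu - x^2 to 1e-3", {
  bd <- sweep_bifurcation(toy_fold(), range = c(-1, 1), n_points = 51)
  expect_gt(nrow(bd$saddle_nodes), 0)
  expect_lt(min(abs(bd$saddle_nodes$value)), 1e-3)
  expect_true(all(bd$saddle_nodes$width <= 2 / 1e4 + 1e-12))
})

test_that("sweep folds match the analytic cubic fold locations", {
  bd <- sweep_bifurcation(toy_cubic(), range = c(-1, 1), n_points = 51)
  mu_star <- cubic_fold_mu(1)
  sn1 <- diagram_fold(bd, "SN1")
  sn2 <- diagram_fold(bd, "SN2")
  expect_equal(sn1, mu_star, tolerance = 1e-3)
  expect_equal(sn2, -mu_star, tolerance = 1e-3)
  iv <- bd$bistable_interval
  expect_equal(iv[1], -mu_star, tolerance = 1e-3)
  expect_equal(iv[2], mu_star, tolerance = 1e-3)
  # inside the window: 3 equilibria (2 stable); outside: 1 stable
  inside <- which(bd$values > iv[1] + 0.05 & bd$values < iv[2] - 0.05)
  outside <- which(bd$values < iv[1] - 0.05 | bd$values > iv[2] + 0.05)
  expect_true(all(bd$n_total[inside] == 3))
  expect_true(all(bd$n_stable[inside] == 2))
  expect_true(all(bd$n_stable[outside] == 1))
})

test_that("branch tracing agrees with the sweep on fold locations", {
  th <- find_threshold(toy_cubic(), "mu", c(-1, 1))
  expect_equal(th$threshold, cubic_fold_mu(1), tolerance = 1e-3)
  # high branch traced downward hits the mirror fold
  m <- toy_cubic(mu = 1)
  hs <- settle(m, init = c(x = 1.5))
  tr <- neurocycle:::trace_branch(m, "mu", 1, -1, hs)
  expect_false(tr$reached_end)
  expect_equal(tr$fold, -cubic_fold_mu(1), tolerance = 1e-3)
})

test_that("quasi-static ramps reproduce the hysteresis loop of the sweep", {
  m <- toy_cubic()
  bd <- sweep_bifurcation(m, range = c(-1, 1), n_points = 51)
  sn1 <- diagram_fold(bd, "SN1")
  sn2 <- diagram_fold(bd, "SN2")
  mus <- seq(-1, 1, by = 0.02)
  x <- settle(set_params(m, mu = -1), init = c(x = -1))
  up <- vapply(mus, function(mu) {
    x <<- settle(set_params(m, mu = mu), init = x, t_end = 400)
    x[["x"]]
  }, numeric(1))
  down <- rev(vapply(rev(mus), function(mu) {
    x <<- settle(set_params(m, mu = mu), init = x, t_end = 400)
    x[["x"]]
  }, numeric(1)))
  jump_up <- mus[which(diff(up > 0) == 1)]      # low -> high branch
  jump_down <- mus[which(diff(down > 0) == 1)]  # high branch lost below
  expect_lt(abs(jump_up - sn1), 0.021)
  expect_lt(abs(jump_down - sn2), 0.021)
})

test_that("two-parameter loci are flat when the second parameter is inert", {
  m <- toy_cubic(extra = c(inert = 1))
  tp <- two_parameter_scan(m, "mu", c(-1, 1), "inert", c(0.5, 1, 2),
                           n_points = 51)
  expect_equal(length(unique(round(tp$loci$sn1, 6))), 1)
  expect_length(tp$cusp_points, 0)
})

test_that("fold loci move with the second parameter and vanish at a cusp", {
  # dx/dt = mu + (b - 0.5) x - x^3: fold pair exists only for b > 0.5
  m <- model_spec("shifted", "x", c(mu = 0, b = 1),
                  c(x = "mu + (b - 0.5) * x - x^3"),
                  init = c(x = 0), input_param = "mu")
  tp <- two_parameter_scan(m, "mu", c(-1, 1), "b", c(1.5, 1, 0.2),
                           n_points = 51)
  sn1 <- tp$loci$sn1
  expect_false(is.na(sn1[1]) || is.na(sn1[2]))
  expect_gt(sn1[1], sn1[2])        # weaker slope -> folds move inward
  expect_true(is.na(sn1[3]))       # fold pair gone below the cusp
  expect_length(tp$cusp_points, 1)
  expect_equal(tp$cusp_points, 0.6, tolerance = 1e-6)  # midpoint of 1, 0.2
})

test_that("control values without any equilibrium are flagged incomplete", {
  m <- model_spec("runaway", "x", c(mu = 0), c(x = "mu + x^2"),
                  init = c(x = 0), input_param = "mu")
  bd <- suppressWarnings(
    sweep_bifurcation(m, range = c(-1, 1), n_points = 51))
  expect_gt(length(bd$incomplete), 0)
  expect_true(all(bd$incomplete > 0))
})

test_that("irreversibility is read off the diagram correctly", {
  # fold normal form shifted so the pair straddles zero: reversible on
  # [0, 1] because the deactivation fold sits inside the scanned range
  m <- toy_cubic()
  bd_rev <- sweep_bifurcation(m, range = c(-1, 1), n_points = 51)
  expect_false(is_irreversible(bd_rev))
  # scanning only mu >= -0.2 leaves SN2 outside: irreversible from there
  bd_irr <- sweep_bifurcation(m, range = c(-0.2, 1), n_points = 51)
  expect_true(is_irreversible(bd_irr))
})
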