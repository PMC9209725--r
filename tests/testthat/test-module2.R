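# Structural checks for the redox-switch module; the full battery runs in
# the acceptance suite.

test_that("the module builds and bounds its fraction states", {
  m <- build_module2()
  expect_length(m$state_names, 11)
  expect_equal(m$input_param, "Abeta")
  tr <- integrate_model(m, init = m$anchors$path,
                        times = seq(0, 500, by = 5))
  expect_lte(max(tr$states[, "RbPP"]), m$params[["Rb_T"]] + 1e-8)
  expect_lte(max(tr$states[, "Cdh1dp"]), m$params[["Cdh1_T"]] + 1e-8)
  expect_gte(min(tr$states), -1e-9)
})

test_that("classification keys on the ROS marker", {
  st <- settle(build_module2())
  expect_equal(classify_module2(st), "normal")
  st["ROS"] <- 5
  expect_equal(classify_module2(st), "pathological")
  expect_equal(classify_module2(st, thresholds = list(ros = 10)), "normal")
})

test_that("calpain activation is cooperative with exponent 2", {
  m <- build_module2()
  a1 <- model_aux(m, replace(m$init, "Ca", 0.05))[["hill_ca"]]
  a2 <- model_aux(m, replace(m$init, "Ca", 0.1))[["hill_ca"]]
  # far below the half-saturation the Hill(2) response is ~quadratic
  expect_equal(a2 / a1, 4, tolerance = 0.1)
})

test_that("p25 turns over more slowly than its production scale", {
  p <- module2_params()
  expect_lt(p[["k_dp25"]], p[["k_sp25"]])
})
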