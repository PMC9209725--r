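# Structural checks for the ERK-switch module; the full perturbation
# battery runs in the acceptance suite.

test_that("the module builds with validated parameters", {
  m <- build_module1()
  expect_s3_class(m, "model_spec")
  expect_length(m$state_names, 12)
  expect_equal(m$input_param, "Abeta")
  expect_error(build_module1(c(Abeta = 0)), "parameters missing")
  expect_error(build_module1(module1_params(ERK_T = 0)), "ERK_T")
})

test_that("the default initial condition honours the conserved totals", {
  m <- build_module1()
  W <- neurocycle:::conservation_matrix(m)
  expect_equal(as.numeric(W %*% m$init),
               unname(neurocycle:::conservation_totals(m)))
})

test_that("classification follows the ERK threshold", {
  zeros <- stats::setNames(rep(0, 12), build_module1()$state_names)
  expect_equal(classify_module1(zeros), "normal")
  hi <- zeros; hi["ERKa"] <- 0.9
  expect_equal(classify_module1(hi), "pathological")
  # configurable threshold
  expect_equal(classify_module1(hi, thresholds = list(erk = 0.95)), "normal")
})

test_that("fast complex formation dwarfs the transport/turnover scale", {
  p <- module1_params()
  assoc <- p[c("ka_pc", "ka_cki", "ka_cycd", "ka_ckid")]
  slow <- p[c("k_incki", "k_expc", "k_int", "k_dcycd", "k_scycd")]
  expect_true(min(assoc) >= 10 * max(slow))
})

test_that("resting trajectories keep every pool non-negative", {
  m <- build_module1()
  tr <- integrate_model(m, times = seq(0, 1000, by = 10))
  expect_gte(min(tr$states), -1e-9)
  expect_lte(max(tr$states[, "ERKa"]), m$params[["ERK_T"]] + 1e-8)
})
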