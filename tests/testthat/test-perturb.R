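test_that("perturbations return fresh parameter sets", {
  p <- c(k_sgls = 0.1, k_sca = 2)
  gls_ko <- scenario("gls_KO", list(k_sgls = 0))
  p2 <- apply_perturbation(p, gls_ko)
  expect_equal(p2[["k_sgls"]], 0)
  expect_equal(p2[["k_sca"]], 2)
  expect_equal(p[["k_sgls"]], 0.1)   # original untouched
})

test_that("the empty scenario is the identity", {
  p <- module1_params()
  expect_identical(apply_perturbation(p, scenario("none")), p)
})

test_that("unknown override keys raise a configuration error", {
  expect_error(
    apply_perturbation(c(a = 1, b = 2), scenario("bad", list(zz = 0))),
    "unknown parameter.*zz.*valid names")
})

test_that("knockout presets encode the stated conventions", {
  m2 <- module2_scenarios()
  expect_equal(unname(m2$gls_KO$overrides["k_sgls"]), 0)
  expect_setequal(names(m2$cycb_KO$overrides), c("k_scycb", "k_scyc"))
  expect_true(all(m2$cycb_KO$overrides == 0))
  m1 <- module1_scenarios()
  expect_equal(unname(m1$p27_KO$overrides["CDKI_T"]), 0)
  expect_equal(unname(m1$MEK_inhibition$overrides["k_aerk"]), 0)
})

test_that("apply_scenario perturbs a model in place", {
  m <- build_module2()
  m2 <- apply_scenario(m, module2_scenarios()$p25_inhibition)
  expect_equal(m2$params[["k_sp25"]], 0)
  expect_gt(m$params[["k_sp25"]], 0)
})
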