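# Structural checks for the DNA-damage module; the full battery runs in
# the acceptance suite.

test_that("the module builds with a conserved Rb chain", {
  m <- build_module3()
  expect_length(m$state_names, 12)
  expect_equal(m$input_param, "DNA_damage")
  tr <- integrate_model(m, times = seq(0, 1000, by = 10),
                        input_step = list(time = 200, param = "DNA_damage",
                                          value = 0.5))
  expect_lt(max(conservation_drift(tr, m)), 1e-6)
  expect_gte(min(tr$states), -1e-9)
})

test_that("damage multipliers are neutral at zero damage", {
  m <- build_module3()
  aux <- model_aux(m, m$init)
  expect_equal(unname(aux[["g53"]]), 1)
  expect_equal(unname(aux[["gE2F"]]), 1)
})

test_that("stoichiometric buffering releases E2F only past the Rb pool", {
  m <- build_module3()
  x <- m$init
  x["FT"] <- 0.3                      # total E2F below the Rb pool
  expect_lt(model_aux(m, x)[["E2F_free"]], 0.01)
  x["R0"] <- 0.05; x["R2"] <- 0.95    # Rb hyperphosphorylated
  expect_gt(model_aux(m, x)[["E2F_free"]], 0.2)
})

test_that("classification distinguishes the three fates", {
  m <- build_module3()
  expect_equal(classify_module3(settle(m)), "quiescent")
  expect_equal(classify_module3(m$anchors$reentry), "repair")
  expect_equal(classify_module3(m$anchors$apoptotic), "apoptotic")
})
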