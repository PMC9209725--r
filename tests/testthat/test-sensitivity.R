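test_that("threshold fold change matches the cubic closed form", {
  # fold at mu* = 2 / (3 sqrt(3 cc)); cc -> 1.1 cc scales it by 1.1^(-1/2)
  sr <- sensitivity_scan(toy_cubic(), range = c(-1, 1), params = "cc")
  up <- sr$results[sr$results$direction == "+10%", ]
  dn <- sr$results[sr$results$direction == "-10%", ]
  expect_equal(up$fold_change, 1.1^0.5, tolerance = 2e-3)     # ~1.0488
  expect_equal(dn$fold_change, 0.9^-0.5, tolerance = 2e-3)    # ~1.0541
  expect_equal(sr$baseline_threshold, cubic_fold_mu(1), tolerance = 1e-3)
})

test_that("a parameter absent from the RHS has fold change exactly 1", {
  m <- toy_cubic(extra = c(inert = 5))
  sr <- sensitivity_scan(m, range = c(-1, 1), params = c("inert", "cc"))
  inert <- sr$results[sr$results$parameter == "inert", ]
  expect_true(all(inert$fold_change == 1))
  expect_false(any(inert$above_2fold))
})

test_that("fold changes are >= 1 and the 2-fold counts partition", {
  sr <- sensitivity_scan(toy_cubic(), range = c(-1, 1),
                         params = c("cc", "mu")[1])
  expect_true(all(sr$results$fold_change >= 1))
  expect_equal(sr$n_below_2fold + sr$n_above_2fold, sr$n_params)
})

test_that("a fold escaping the scan range gives infinite fold change", {
  # the q^20 slope makes a +10% variation launch the fold far beyond the
  # scanned window; the conservative convention reports infinity
  m <- model_spec("fragile", "x", c(mu = 0, q = 1),
                  c(x = "mu + q^20 * x - x^3"),
                  init = c(x = 0), input_param = "mu")
  sr <- sensitivity_scan(m, range = c(-1, 1), params = "q")
  up <- sr$results[sr$results$direction == "+10%", ]
  expect_true(is.infinite(up$fold_change))
  expect_true(up$above_2fold)
  dn <- sr$results[sr$results$direction == "-10%", ]
  expect_true(is.finite(dn$fold_change))
})
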