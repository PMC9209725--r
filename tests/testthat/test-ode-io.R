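test_that("exported .ode text has the expected structure", {
  m <- build_module1()
  lines <- export_ode(m)
  for (st in m$state_names) {
    expect_true(any(startsWith(lines, paste0("d", st, "/dt="))))
  }
  expect_true(any(startsWith(lines, "par k_aerk=")))
  expect_true(any(startsWith(lines, "init ERKa=")))
  expect_true(any(grepl("^aux p27_total=", lines)))   # conserved total
  expect_equal(lines[length(lines)], "done")
})

test_that("unsupported RHS constructs are rejected at export", {
  m <- model_spec("odd", "x", c(k = 1), c(x = "-k * max(x, 0)"),
                  init = c(x = 1))
  expect_error(export_ode(m), "not exportable.*max")
})

test_that("a model round-trips through .ode text to 1e-8", {
  m <- build_module2()
  f <- tempfile(fileext = ".ode")
  export_ode(m, file = f)
  m2 <- parse_ode(f)
  expect_setequal(m2$state_names, m$state_names)
  expect_equal(m2$params[names(m$params)], m$params)
  times <- seq(0, 300, by = 3)
  init <- m$init
  init["Ca"] <- 0.5    # off-equilibrium so the comparison is non-trivial
  t1 <- integrate_model(m, init = init, times = times)
  t2 <- integrate_model(m2, init = init[m2$state_names], times = times)
  expect_lt(max(abs(t1$states - t2$states[, colnames(t1$states)])), 1e-8)
})

test_that("flat key = value configs round-trip with namespaces", {
  p <- module2_params()
  f <- tempfile(fileext = ".cfg")
  write_params(p, f, namespace = "m2", header = "redox module defaults")
  back <- read_params(f, namespace = "m2")
  expect_equal(back, p)
  expect_length(read_params(f, namespace = "m1"), 0)
  writeLines(c("a = 1", "broken line"), f)
  expect_error(read_params(f), "malformed")
})

test_that("scenario files parse into scenario objects", {
  f <- tempfile(fileext = ".ini")
  writeLines(c(
    "# rescue battery",
    "[gls_KO]",
    "description = glutaminase knockout",
    "expect = reversible transition",
    "k_sgls = 0",
    "[double_KO]",
    "k_sgls = 0",
    "k_scycb = 0",
    "k_scyc = 0"), f)
  sc <- read_scenarios(f)
  expect_named(sc, c("gls_KO", "double_KO"))
  expect_equal(unname(sc$gls_KO$overrides["k_sgls"]), 0)
  expect_equal(sc$gls_KO$expect, "reversible transition")
  expect_length(sc$double_KO$overrides, 3)
})

test_that("trajectory and diagram TSV writers record provenance", {
  m <- toy_decay()
  tr <- integrate_model(m, times = seq(0, 1, by = 0.5))
  f <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f, seed = 7)
  lines <- readLines(f)
  expect_match(lines[1], "# model=decay seed=7")
  tab <- utils::read.delim(f, comment.char = "#")
  expect_named(tab, c("time", "x"))

  bd <- sweep_bifurcation(toy_fold(), range = c(-1, 1), n_points = 51)
  f2 <- tempfile(fileext = ".tsv")
  write_diagram(bd, f2, seed = 7)
  expect_match(readLines(f2)[1], "# control=mu seed=7")
})

test_that("the shipped scenario file matches the in-code presets", {
  f <- system.file("extdata", "module2_scenarios.ini",
                   package = "neurocycle")
  sc <- read_scenarios(f)
  presets <- module2_scenarios()
  expect_setequal(names(sc), names(presets))
  for (nm in names(sc)) {
    expect_equal(sc[[nm]]$overrides, presets[[nm]]$overrides)
  }
  # every override resolves against the module's parameter set
  p <- module2_params()
  for (s in sc) expect_silent(apply_perturbation(p, s))
})
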