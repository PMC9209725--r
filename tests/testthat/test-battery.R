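test_that("an empty battery yields an empty report", {
  rep <- run_scenario_battery(list())
  expect_equal(nrow(rep), 0)
  expect_named(rep, c("name", "module", "scenario", "expected", "observed",
                      "pass"))
})

test_that("pass flags reflect the predicates and errors become failures", {
  bat <- list(
    neurocycle:::battery_entry("good", "toy", NULL, "passes",
      function(entry, ...) list(observed = "fine", pass = TRUE)),
    neurocycle:::battery_entry("bad", "toy", scenario("s", list()), "fails",
      function(entry, ...) list(observed = "nope", pass = FALSE)),
    neurocycle:::battery_entry("broken", "toy", NULL, "errors",
      function(entry, ...) stop("boom")))
  rep <- run_scenario_battery(bat)
  expect_equal(rep$pass, c(TRUE, FALSE, FALSE))
  expect_match(rep$observed[3], "ERROR: boom")
  expect_equal(rep$scenario, c("none", "s", "none"))
})

test_that("battery reports can be written as TSV", {
  f <- tempfile(fileext = ".tsv")
  bat <- list(neurocycle:::battery_entry("one", "toy", NULL, "x",
    function(entry, ...) list(observed = "ok", pass = TRUE)))
  run_scenario_battery(bat, file = f)
  tab <- utils::read.delim(f)
  expect_equal(tab$name, "one")
  expect_true(tab$pass)
})
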