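test_that("planted factors hit the target trait correlation exactly", {
  sim <- simulate_expression(50, 30,
    sets = list(list(size = 8, loading = 1, r = 0.4),
                list(size = 8, loading = 1, r = -0.7)),
    noise_sd = 0.3, seed = 2)
  expect_equal(stats::cor(sim$factors[[1]], sim$trait), 0.4,
               tolerance = 1e-12)
  expect_equal(stats::cor(sim$factors[[2]], sim$trait), -0.7,
               tolerance = 1e-12)
  expect_equal(mean(sim$trait), 0.5)   # balanced labels
})

test_that("noise-free unit-loading sets recover the target correlation", {
  sim <- simulate_expression(30, 40,
    sets = list(list(size = 10, loading = 1, r = 0.55)),
    noise_sd = 0, seed = 4)
  eg <- compute_eigengene(sim$matrix, sim$gene_sets[[1]])
  ct <- correlate_trait(eg$scores, sim$trait)
  expect_equal(abs(ct$r), 0.55, tolerance = 1e-6)
})

test_that("generation is seed-deterministic and preserves the caller RNG", {
  set.seed(99)
  before <- .Random.seed
  a <- simulate_expression(20, 10, noise_sd = 0.1, seed = 7)
  expect_identical(.Random.seed, before)
  b <- simulate_expression(20, 10, noise_sd = 0.1, seed = 7)
  expect_identical(a$matrix, b$matrix)
  c <- simulate_expression(20, 10, noise_sd = 0.1, seed = 8)
  expect_false(identical(a$matrix, c$matrix))
})

test_that("infeasible specifications are rejected", {
  expect_error(simulate_expression(10, 10,
    sets = list(list(size = 5, loading = 1, r = 1.2))), "\\[-1, 1\\]")
  expect_error(simulate_expression(4, 10,
    sets = list(list(size = 5, loading = 1, r = 0))), "larger than")
  expect_error(simulate_expression(10, 7), "n_samples")
})

test_that("observation noise overlays a reproducible deterministic path", {
  m <- toy_decay()
  clean <- simulate_noisy_trajectory(m, obs_noise_sd = 0, seed = 1,
                                     times = seq(0, 1, by = 0.1))
  expect_identical(clean$states, clean$states_clean)
  n1 <- simulate_noisy_trajectory(m, obs_noise_sd = 0.05, seed = 1,
                                  times = seq(0, 1, by = 0.1))
  n2 <- simulate_noisy_trajectory(m, obs_noise_sd = 0.05, seed = 2,
                                  times = seq(0, 1, by = 0.1))
  expect_identical(n1$states_clean, n2$states_clean)
  expect_false(identical(n1$states, n2$states))
  expect_identical(n1$states,
                   simulate_noisy_trajectory(m, obs_noise_sd = 0.05,
                                             seed = 1,
                                             times = seq(0, 1, by = 0.1))$states)
})

test_that("state classification tolerates 5% observation noise", {
  m <- build_module1()
  rest <- settle(m)
  m_hi <- set_params(m, Abeta = 0.05)
  path <- settle(m_hi, init = rest)
  hits <- 0
  for (seed in 1:20) {
    tr <- simulate_noisy_trajectory(m_hi, obs_noise_sd = 0.05, seed = seed,
                                    init = path,
                                    times = seq(0, 50, by = 5))
    if (classify_module1(tr) == "pathological") hits <- hits + 1
  }
  expect_gte(hits, 19)
})
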