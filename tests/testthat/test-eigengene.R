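test_that("quantile normalization reproduces the hand-worked 2x2 example", {
  x <- matrix(c(1, 3, 4, 2), 2, 2)     # columns (1,3) and (4,2)
  qn <- quantile_normalize(x)
  expect_equal(qn, matrix(c(1.5, 3.5, 3.5, 1.5), 2, 2))
})

test_that("identical columns are unchanged and ties map to rank means", {
  x <- matrix(c(1, 2, 3, 1, 2, 3), 3, 2)
  expect_equal(quantile_normalize(x), x)
  y <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  qy <- quantile_normalize(y)
  expect_equal(unname(qy[, 1]), c(3, 3.5, 4))      # row means of sorted cols
  expect_equal(unname(qy[, 2]), rep(3.5, 3))       # tied ranks averaged
})

test_that("log transform guards against negative values", {
  expect_error(quantile_normalize(matrix(c(-1, 1, 2, 3), 2, 2), log2 = TRUE),
               "negative")
  qn <- quantile_normalize(matrix(c(1, 3, 3, 1), 2, 2), log2 = TRUE)
  expect_equal(unname(qn[1, 1]), log2(1 + 1))
  expect_equal(unname(qn[2, 1]), log2(3 + 1))
})

test_that("a rank-1 gene set yields variance explained 1", {
  g1 <- c(1, 2, 5, 3, 8, 4)
  x <- rbind(gene1 = g1, gene2 = 2 * g1)
  eg <- compute_eigengene(x, c("gene1", "gene2"))
  expect_equal(eg$var_explained, 1, tolerance = 1e-12)
  expect_equal(unname(eg$scores), as.numeric(scale(g1)), tolerance = 1e-10)
  expect_equal(mean(eg$scores), 0, tolerance = 1e-12)
  expect_equal(stats::sd(eg$scores), 1, tolerance = 1e-12)
})

test_that("proportional genes give the standardized shared profile", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  eg <- compute_eigengene(x, c("a", "b"))
  expect_equal(unname(eg$scores), as.numeric(scale(1:4)), tolerance = 1e-10)
  expect_gte(stats::cor(eg$scores, colMeans(t(scale(t(x))))), 0)
})

test_that("eigengene scores match a brute-force SVD reference to 1e-10", {
  set.seed(11)
  for (rep in 1:3) {
    x <- matrix(rnorm(20 * 30), 20, 30,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:30)))
    eg <- compute_eigengene(x, rownames(x))
    z <- t(scale(t(x)))
    ev <- eigen(crossprod(z), symmetric = TRUE)     # independent route
    ref <- as.numeric(scale(ev$vectors[, 1]))
    err <- min(max(abs(eg$scores - ref)), max(abs(eg$scores + ref)))
    expect_lt(err, 1e-10)
    expect_equal(eg$var_explained, ev$values[1] / sum(ev$values),
                 tolerance = 1e-10)
  }
})

test_that("the eigengene is invariant to gene order and sample relabeling", {
  set.seed(12)
  x <- matrix(rnorm(10 * 16), 10, 16,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:16)))
  eg1 <- compute_eigengene(x, rownames(x))
  eg2 <- compute_eigengene(x[sample(10), ], rownames(x))
  expect_equal(eg1$scores, eg2$scores, tolerance = 1e-10)
  perm <- sample(16)
  eg3 <- compute_eigengene(x[, perm], rownames(x))
  expect_equal(unname(eg3$scores), unname(eg1$scores[perm]),
               tolerance = 1e-10)
})

test_that("degenerate gene sets are handled as specified", {
  x <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("g1", "g2", "flat"), paste0("s", 1:4)))
  x["flat", ] <- 5
  expect_error(compute_eigengene(x, c("g1", "missing1", "missing2")),
               "fewer than 2.*missing1")
  expect_warning(eg <- compute_eigengene(x, rownames(x), min_genes = 2),
                 "zero-variance")
  expect_equal(eg$n_genes_used, 2)
})

test_that("trait correlation reproduces the df = 2 worked example", {
  ct <- correlate_trait(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(ct$r, 2 / sqrt(5), tolerance = 1e-12)
  expect_equal(ct$t, 2 * sqrt(2), tolerance = 1e-10)
  expect_equal(ct$df, 2)
  # closed form for the df = 2 t CDF: F(t) = 1/2 + t / (2 sqrt(2 + t^2))
  p_closed <- 2 * (1 - (0.5 + ct$t / (2 * sqrt(2 + ct$t^2))))
  expect_equal(ct$p, p_closed, tolerance = 1e-12)
  expect_equal(ct$p, 0.10557, tolerance = 1e-4)
})

test_that("orthogonal scores give r = 0, p = 1", {
  ct <- correlate_trait(c(-1, 1, -1, 1), c(1, 1, 0, 0))
  expect_equal(ct$r, 0)
  expect_equal(ct$p, 1)
})

test_that("perfect correlation is flagged exact with p = 0", {
  ct <- correlate_trait(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(ct$r, 1)
  expect_equal(ct$p, 0)
  expect_true(ct$exact)
})

test_that("degenerate traits are rejected", {
  expect_error(correlate_trait(1:4, c(1, 1, 1, 1)), "constant")
  expect_error(correlate_trait(1:2, c(0, 1)), "at least 3")
})

test_that("p values match the numerically integrated t density to 1e-8", {
  for (r in c(0.2, 0.5, 0.8)) {
    for (n in c(5, 10, 30)) {
      scores <- seq_len(n)
      # build a trait with approximately this correlation; use the actual r
      t_val <- r * sqrt(n - 2) / sqrt(1 - r^2)
      p_num <- 2 * stats::integrate(function(u) stats::dt(u, df = n - 2),
                                    t_val, Inf, rel.tol = 1e-12)$value
      p_pkg <- 2 * stats::pt(t_val, df = n - 2, lower.tail = FALSE)
      expect_equal(p_pkg, p_num, tolerance = 1e-8)
    }
  }
})

test_that("gene-set association tables mirror the per-set results", {
  sim <- simulate_expression(60, 40,
    sets = list(list(size = 10, loading = 1, r = 0.6),
                list(size = 10, loading = 1, r = -0.6)),
    noise_sd = 0.2, seed = 5)
  tab <- gene_set_association(sim$matrix, sim$trait, sim$gene_sets)
  expect_equal(nrow(tab), 2)
  expect_gt(tab$r[1], 0.3)
  expect_lt(tab$r[2], -0.3)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  # empty set list gives an empty table
  empty <- gene_set_association(sim$matrix, sim$trait, list())
  expect_equal(nrow(empty), 0)
})

test_that("GMT and plain gene-set files are read correctly", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), f)
  gs <- read_gene_sets(f)
  expect_named(gs, c("setA", "setB"))
  expect_equal(gs$setA, c("g1", "g2", "g3"))
  f2 <- tempfile(fileext = ".txt")
  writeLines(c("g1", "g2"), f2)
  expect_equal(read_gene_sets(f2)$set1, c("g1", "g2"))
})

test_that("expression matrices round-trip through TSV", {
  sim <- simulate_expression(10, 6, seed = 3)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(sim$matrix, f, sep = "\t", quote = FALSE,
                     col.names = NA)
  back <- read_expression_matrix(f)
  expect_equal(back, sim$matrix)
})
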