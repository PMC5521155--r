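test_that("compositions enumerate stars-and-bars in lexicographic order", {
  c52 <- compositions(5, 2)
  expect_equal(c52, rbind(c(1L, 4L), c(2L, 3L), c(3L, 2L), c(4L, 1L)))
  expect_equal(nrow(compositions(20, 2)), 19)
  expect_equal(compositions(4, 1), matrix(4L, 1, 1))
  expect_equal(nrow(compositions(7, 3)), choose(6, 2))
  expect_true(all(rowSums(compositions(7, 3)) == 7))
  expect_error(compositions(3, 4), "K <= m")
  expect_error(compositions(40, 10, max_count = 100), "guard")
})

test_that("xi matches an independent normal-tail evaluation and is zero at T = 0", {
  # chi^2_1 survival at x equals 2*Phi(-sqrt(x)): an independent route
  t <- c(1, 2)
  expected <- -2 * (log(2 * pnorm(-1)) + log(2 * pnorm(-2)))
  expect_equal(xi_statistic(t, c(1, 1)), expected, tolerance = 1e-12)
  expect_equal(xi_statistic(rep(0, 6), c(2, 4)), 0)
  expect_gte(xi_statistic(rnorm(5), c(3, 2)), 0)
  expect_error(xi_statistic(rnorm(4), c(2, 3)), "sum")
  # huge signals stay finite via the log-survival path
  expect_true(is.finite(xi_statistic(c(50, rep(0, 4)), c(1, 4))))
})

test_that("max_xi agrees with exhaustive enumeration and isolates dominant blocks", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      t <- rnorm(6)
      brute <- max(apply(compositions(6, 2), 1, function(p) xi_statistic(t, p)))
      expect_equal(max_xi(t, 2)$xi, brute, tolerance = 1e-12)
      brute3 <- max(apply(compositions(6, 3), 1, function(p) xi_statistic(t, p)))
      expect_equal(max_xi(t, 3)$xi, brute3, tolerance = 1e-12)
    }
  })
  # one huge leading entry: K=2 maximizer isolates it (checked vs brute force)
  t <- c(8, rnorm(5, sd = 0.3))
  expect_equal(max_xi(t, 2)$parts, c(1, 5))
  expect_equal(max_xi(t, 1)$xi, xi_statistic(t, 6))
})

test_that("the null distribution is seed-reproducible and marker-free", {
  n1 <- gate_null(6, 2, 1000, seed = 99)
  n2 <- gate_null(6, 2, 1000, seed = 99)
  expect_identical(n1$maxxi, n2$maxxi)
  expect_identical(n1$eta, n2$eta)
  expect_true(all(n1$eta >= 0 & n1$eta <= 1))
  expect_false(identical(n1$eta, gate_null(6, 2, 1000, seed = 100)$eta))
  # cache round trip
  d <- withr::local_tempdir()
  n3 <- gate_null(6, 2, 1000, seed = 99, cache = d)
  expect_identical(n3$eta, n1$eta)
  expect_identical(gate_null(6, 2, 1000, seed = 99, cache = d)$eta, n1$eta)
})

test_that("vectorized per-K maxima agree with the scalar path", {
  withr::with_seed(5, {
    tm <- matrix(rnorm(50 * 7), 50, 7)
    mm <- gatetest:::.maxxi_matrix(tm, 3)
    for (b in c(1, 17, 50)) {
      expect_equal(mm[b, 1], max_xi(tm[b, ], 1)$xi, tolerance = 1e-10)
      expect_equal(mm[b, 2], max_xi(tm[b, ], 2)$xi, tolerance = 1e-10)
      expect_equal(mm[b, 3], max_xi(tm[b, ], 3)$xi, tolerance = 1e-10)
    }
  })
})

test_that("eta0 edge cases: all-zero Wald gives 1, huge signal gives 0", {
  nd <- gate_null(5, 2, 1000, seed = 7)
  r0 <- gate_from_wald(rep(0, 5), nd)
  expect_equal(r0$eta0, 1)
  expect_equal(r0$p_value, 1)
  rs <- gate_from_wald(c(50, 1, 0, 0, 0), nd)
  expect_equal(rs$eta0, 0)
  # the one-layer ECDF includes each draw, so at most k_max null draws tie at
  # eta = 0 and the p-value sits at the resolution floor
  expect_lte(rs$p_value, 2 / 1000)
  rm <- gate_from_wald(c(50, 1, 0, 0, 0), nd, midp = TRUE)
  expect_equal(rm$p_value, (rs$p_value * 1000 + 1) / 1001)
  expect_error(gate_from_wald(rep(0, 4), nd), "does not match")
})

test_that("with a single group count GATE is rank-equivalent to the FCT p-value", {
  nd <- gate_null(8, 1, 2000, seed = 21)
  withr::with_seed(22, {
    tmat <- matrix(rnorm(300 * 8), 300, 8)
    eta0 <- apply(tmat, 1, function(t) gate_from_wald(t, nd)$eta0)
    fct_p <- apply(tmat, 1, function(t) fct_test(t)$p.value)
  })
  # the empirical tail is a step function, so ties at resolution 1/B keep the
  # rank agreement just below exact
  expect_gt(cor(eta0, fct_p, method = "spearman"), 0.999)
  # strict monotonicity on the untied pairs: sorting by FCT p sorts eta0
  expect_true(all(diff(eta0[order(fct_p)]) >= 0))
})

test_that("paper-formula counting is the complement of the default", {
  nd <- gate_null(5, 2, 1000, seed = 31)
  t <- withr::with_seed(32, rnorm(5))
  a <- gate_from_wald(t, nd)
  b <- gate_from_wald(t, nd, paper_formula = TRUE)
  expect_equal(a$p_value + b$p_value, 1)
})

test_that("gate_test p-value is invariant under eigenvector sign flips", {
  y <- make_traits(200, 5, seed = 41)
  g <- make_genotype(200, seed = 42)
  nd <- gate_null(5, 2, 1000, seed = 43)
  pca <- trait_pca(y)
  t0 <- pc_wald(pca, g)
  flips <- withr::with_seed(44, sample(c(-1, 1), 5, replace = TRUE))
  pca2 <- pca
  pca2$vectors <- sweep(pca$vectors, 2, flips, `*`)
  pca2$scores <- sweep(pca$scores, 2, flips, `*`)
  t1 <- pc_wald(pca2, g)
  expect_equal(gate_from_wald(t0, nd)$p_value, gate_from_wald(t1, nd)$p_value)
})

test_that("the end-to-end gate_test returns a well-formed result", {
  sim <- simulate_dataset("S1", n = 400, maf = 0.3, seed = 51)
  nd <- gate_null(20, 2, 1000, seed = 52)
  res <- gate_test(sim$y, sim$g, null = nd)
  expect_s3_class(res, "gate")
  expect_true(res$p.value >= 0 && res$p.value <= 1)
  expect_equal(nrow(res$per_k), 2)
  expect_equal(res$statistic, min(res$per_k$tail))
  expect_output(print(res), "GATE")
})
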