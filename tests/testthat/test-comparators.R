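test_that("FCT has the chi-squared closed form", {
  expect_equal(fct_test(rep(0, 4))$p.value, 1)
  expect_equal(fct_test(c(1, 1))$p.value, exp(-1), tolerance = 1e-12)
  expect_equal(unname(fct_test(c(1, 2, 3))$statistic), 14)
})

test_that("the mCPC split follows the 80% cumulative-variance rule", {
  expect_equal(mcpc_split(c(8, 1, 1)), 1)
  expect_equal(mcpc_split(c(1, 1, 1, 1, 1)), 4)
  expect_equal(mcpc_split(c(0.5, 0.3, 0.2)), 2)
  expect_error(mcpc_split(c(0, 0)), "zero")
  expect_error(mcpc_split(c(1, 2, 3)), "descending")
})

test_that("mCPC equals the two-group xi statistic and degenerates to FCT", {
  withr::with_seed(61, {
    for (i in 1:10) {
      t <- rnorm(6)
      lam <- sort(rexp(6), decreasing = TRUE)
      s <- mcpc_split(lam)
      h <- if (s < 6) mcpc_test(t, lam) else suppressWarnings(mcpc_test(t, lam))
      if (s < 6) expect_equal(unname(h$statistic), xi_statistic(t, c(s, 6 - s)))
    }
  })
  expect_equal(mcpc_test(rep(0, 5), c(0.5, 0.2, 0.2, 0.05, 0.05))$p.value, 1)
  expect_warning(h <- mcpc_test(c(1, 2), c(1, 0.9)), "falling back")
  expect_match(h$method, "Fisher")
})

test_that("MANOVA matches the multivariate-lm oracle and the univariate F reduction", {
  y <- make_traits(80, 3, seed = 71)
  g <- make_genotype(80, seed = 72)
  ours <- manova_test(y, g)
  fit <- lm(y ~ g)
  oracle <- anova(fit, test = "Wilks")
  expect_equal(unname(ours$statistic), oracle["g", "Wilks"], tolerance = 1e-8)
  expect_equal(ours$p.value, oracle["g", "Pr(>F)"], tolerance = 1e-8)
  # m = 1: same p as the squared-t / F test of simple regression
  y1 <- y[, 1, drop = FALSE]
  u <- manova_test(y1, g)
  sf <- summary(lm(y1 ~ g))
  expect_equal(u$p.value, unname(sf$coefficients["g", "Pr(>|t|)"]), tolerance = 1e-10)
  expect_error(manova_test(make_traits(10, 9), make_genotype(10)), "n > m")
})

test_that("p-value correlation mapping has the exact endpoints and is monotone", {
  expect_equal(pvalue_correlation(0), 0, tolerance = 1e-3)
  expect_equal(pvalue_correlation(1), 1, tolerance = 1e-6)
  expect_equal(pvalue_correlation(-0.6), pvalue_correlation(0.6))
  r <- pvalue_correlation(seq(0, 1, 0.1))
  expect_true(all(diff(r) >= 0))
  # Monte-Carlo oracle at r = 0.8
  mc <- withr::with_seed(73, {
    z1 <- rnorm(2e5); z2 <- 0.8 * z1 + sqrt(1 - 0.64) * rnorm(2e5)
    cor(2 * pnorm(-abs(z1)), 2 * pnorm(-abs(z2)))
  })
  expect_equal(pvalue_correlation(0.8), mc, tolerance = 0.02)
})

test_that("TATES reduces to Simes for independent traits and to min-p when perfectly correlated", {
  h <- tates_test(c(0.01, 0.5), diag(2))
  expect_equal(h$p.value, 0.02, tolerance = 1e-6)
  ones <- matrix(1, 3, 3)
  h2 <- tates_test(c(0.3, 0.04, 0.6), ones)
  expect_equal(h2$p.value, 0.04, tolerance = 1e-6)
  expect_error(tates_test(c(0.1, 0.2), matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("univariate per-trait p-values match lm and flag the obvious cases", {
  y <- make_traits(100, 3, seed = 81)
  g <- make_genotype(100, seed = 82)
  p <- univariate_trait_tests(y, g)
  fit <- summary(lm(y[, 2] ~ g))
  expect_equal(unname(p[2]), fit$coefficients["g", "Pr(>|t|)"], tolerance = 1e-10)
  ylinked <- cbind(g + rnorm(100, sd = 0.01), y)
  expect_lt(univariate_trait_tests(ylinked, g)[1], 1e-20)
  # m = 1 agrees with the Wald pipeline under an identity rotation
  y1 <- y[, 1, drop = FALSE]
  p1 <- univariate_trait_tests(y1, g)
  fitp <- summary(lm(y1[, 1] ~ g))
  expect_equal(unname(p1[1]), unname(fitp$coefficients["g", "Pr(>|t|)"]))
})

test_that("the proportional-odds reverse regression is calibrated and handles 2-level genotypes", {
  # binary genotype special case runs as logistic regression
  y <- make_traits(200, 2, seed = 91)
  g01 <- withr::with_seed(92, rbinom(200, 1, 0.3))
  h <- multiphen_test(y, g01)
  expect_true(h$p.value > 0 && h$p.value <= 1)
  expect_equal(unname(h$parameter["df"]), 2)
  # null calibration at m = 1: LRT p uniform over replicates
  pv <- withr::with_seed(93, replicate(400, {
    y1 <- matrix(rnorm(300), 300, 1)
    g <- rbinom(300, 2, 0.3)
    multiphen_test(cbind(y1, rnorm(300)), g)$p.value
  }))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})
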