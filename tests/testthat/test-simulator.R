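test_that("structure specs reproduce the catalogued coefficient patterns", {
  s2 <- structure_spec("S2")
  expect_equal(s2$gamma_tilde, rep(2, 5))
  expect_equal(s2$m, 20L)
  expect_equal(s2$L, 5L)
  s12 <- structure_spec("S12")
  expect_equal(s12$gamma, 1.50 - 0.05 * (0:19))
  s7 <- structure_spec("S7")
  expect_equal(s7$model, 1L)
  expect_equal(s7$m, 100L)
  expect_equal(s7$gamma_tilde, 1 - 0.04 * (0:24))
  expect_equal(structure_spec("S11")$gamma[20], 0.05)
  expect_error(structure_spec("S99"), "unknown")
  # idempotent on an existing spec
  expect_identical(structure_spec(s2), s2)
})

test_that("analytic correlations: block structure, gradients, and published extremes", {
  r3 <- analytic_correlation("S3")
  blocks <- rep(1:5, each = 4)
  expect_equal(unique(round(r3[1:4, 1:4][upper.tri(diag(4))], 3)), 0.500)
  expect_true(all(r3[blocks == 1, blocks == 2] == 0))  # cross-block exactly zero
  expect_equal(round(r3[17, 18], 3), 0.038)
  r9 <- analytic_correlation("S9")
  expect_equal(unique(r9[upper.tri(r9)]), 0.2)
  r11 <- analytic_correlation("S11")
  expect_equal(round(r11[19, 20], 3), 0.005)   # smallest direct-model entry
  expect_equal(round(max(r11[upper.tri(r11)]), 3), 0.487)
  expect_true(all(diag(r11) == 1))
})

test_that("effect sizes round-trip through the explained-variance formulas to 1e-12", {
  for (p in c(0.05, 0.15, 0.3, 0.5)) for (h2 in c(1e-4, 1e-3, 0.01, 0.1)) {
    for (gam in c(0.2, 0.5, 1, 2)) {
      b <- solve_beta_model1(h2, p, gam)
      back <- 2 * p * (1 - p) * b^2 * gam^2 / (1 + gam^2 + 2 * p * (1 - p) * b^2 * gam^2)
      expect_equal(back, h2, tolerance = 1e-12)
    }
    grow <- c(0.8, 0.3)
    b2 <- solve_beta_model2(h2, p, grow)
    back2 <- 2 * p * (1 - p) * b2^2 / (sum(grow^2) + 1 + 2 * p * (1 - p) * b2^2)
    expect_equal(back2, h2, tolerance = 1e-12)
  }
  expect_equal(solve_beta_model1(0.001, 0.5, 1), 0.063277, tolerance = 1e-4)
  expect_equal(solve_beta_model1(0, 0.3, 1), 0)
  expect_equal(solve_beta_model2(0, 0.3, 1), 0)
  expect_error(solve_beta_model1(0.01, 0.3, 0), "gamma = 0")
})

test_that("genotypes follow Hardy-Weinberg frequencies and are seed-stable", {
  g <- simulate_genotypes(2e5, 0.05, seed = 101)
  expect_equal(mean(g), 2 * 0.05, tolerance = 0.005)
  p2 <- mean(g == 2)
  expect_lt(abs(p2 - 0.0025), 3 * sqrt(0.0025 * 0.9975 / 2e5))
  expect_identical(simulate_genotypes(100, 0.3, seed = 5), simulate_genotypes(100, 0.3, seed = 5))
  expect_error(simulate_genotypes(100, 0.7), "maf")
})

test_that("null simulations reproduce the analytic correlation matrices", {
  d1 <- simulate_dataset("S1", n = 5e4, maf = 0.3, seed = 111)
  dev1 <- max(abs(cor(d1$y) - analytic_correlation("S1")))
  expect_lt(dev1, 0.02)
  # cross-block empirical correlations are centred on zero
  blocks <- rep(1:5, each = 4)
  cross <- cor(d1$y)[blocks == 1, blocks == 5]
  expect_lt(max(abs(cross)), 0.02)
  d10 <- simulate_dataset("S10", n = 5e4, maf = 0.3, seed = 112)
  expect_lt(max(abs(cor(d10$y) - analytic_correlation("S10"))), 0.02)
})

test_that("solved effect sizes deliver the target per-trait explained variance", {
  # generate one trait directly from the model equations at large n
  n <- 1e6; p <- 0.15; h2 <- 0.001; gam <- 1
  r2 <- withr::with_seed(121, {
    b <- solve_beta_model1(h2, p, gam)
    g <- rbinom(n, 2, p)
    y1 <- (g * b + rnorm(n)) * gam + rnorm(n)
    summary(lm(y1 ~ g))$r.squared
  })
  expect_lt(abs(r2 - h2) / h2, 0.10)
  r2b <- withr::with_seed(122, {
    b <- solve_beta_model2(0.002, p, 0.5)
    g <- rbinom(n, 2, p)
    y1 <- rnorm(n) * 0.5 + g * b + rnorm(n)
    summary(lm(y1 ~ g))$r.squared
  })
  expect_lt(abs(r2b - 0.002) / 0.002, 0.10)
})

test_that("association assignment activates whole latent blocks and is reproducible", {
  d <- simulate_dataset("S3", n = 50, maf = 0.3, h2 = 0.001, lambda = 0.6, seed = 131)
  expect_equal(d$associated, 1:12)
  expect_equal(which(d$beta != 0), 1:3)         # first three latents active
  expect_error(simulate_dataset("S3", n = 50, maf = 0.3, h2 = 0.001, lambda = 0.55),
               "multiple of the block size")
  dr1 <- simulate_dataset("S3", n = 50, maf = 0.3, h2 = 0.001, lambda = 0.4,
                          assignment = "random", seed = 132)
  dr2 <- simulate_dataset("S3", n = 50, maf = 0.3, h2 = 0.001, lambda = 0.4,
                          assignment = "random", seed = 132)
  expect_identical(dr1$associated, dr2$associated)
  expect_length(dr1$associated, 8)
  # random assignment still activates whole blocks under Model 1
  expect_true(all(table(structure_spec("S3")$blocks[dr1$associated]) == 4))
  d2 <- simulate_dataset("S9", n = 50, maf = 0.3, h2 = 0.002, lambda = 0.2, seed = 133)
  expect_equal(which(d2$beta != 0), 1:4)
})
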