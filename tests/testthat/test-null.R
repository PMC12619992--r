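test_that("asymptotic null has a proper, monotone upper tail centered at zero", {
  nul <- build_null_asymptotic(1000, c(0.7, 0.2, 0.1))
  tails <- vapply(c(-1, 0, 1, 5, 20), nul$tail_fn, numeric(1))
  expect_true(all(diff(tails) <= 0))
  expect_true(all(tails >= 0 & tails <= 1))
  expect_lt(nul$tail_fn(1e6), 1e-6)
  expect_gt(nul$tail_fn(-1e3), 1 - 1e-6)
  expect_equal(unname(nul$support_summary["mean"]), 0)
  # tail at the mean of a centered law is interior
  expect_gt(nul$tail_fn(0), 0.2)
  expect_lt(nul$tail_fn(0), 0.8)
})

test_that("degenerate margins are rejected", {
  expect_error(build_null_asymptotic(100, c(1)), "identically zero")
  expect_error(build_null_asymptotic(3, c(0.5, 0.5)), "n >= 4")
})

test_that("permutation null is seeded, reproducible, and zero for constant genes", {
  x <- runif(60)
  y <- rnbinom(60, mu = 1, size = 1)
  p1 <- build_null_permutation(x, y, B = 200, seed = 5)
  p2 <- build_null_permutation(x, y, B = 200, seed = 5)
  expect_identical(p1$draws, p2$draws)
  expect_true(all(abs(p1$draws) <= 1))
  p3 <- build_null_permutation(x, rep(2, 60), B = 50, seed = 1)
  expect_true(all(p3$draws == 0))
})

test_that("permutation draws of the scaled statistic match the asymptotic law", {
  set.seed(11)
  n <- 2000
  x <- runif(n)
  y <- rnbinom(n, mu = 0.8, size = 1)
  nul <- build_null_asymptotic(n, tie_profile(y))
  pn <- build_null_permutation(x, y, B = 10000, seed = 21)
  sc <- n * pn$draws
  # mean of the represented law is 0 within 3 standard errors
  expect_lt(abs(mean(sc)), 3 * sd(sc) / sqrt(length(sc)))
  # variance agreement
  expect_equal(sd(sc), sqrt(nul$support_summary[["variance"]]),
               tolerance = 0.05)
  # quantile agreement at 0.5 / 0.9 / 0.99 (absolute, Monte-Carlo scale)
  for (q in c(0.5, 0.9, 0.99)) {
    emp <- quantile(sc, q, names = FALSE)
    expect_lt(abs(nul$tail_fn(emp) - (1 - q)), 0.015)
  }
})

test_that("p-values are proper, monotone in the statistic, and deep for strong signal", {
  n <- 200
  set.seed(2)
  x <- runif(n)
  y <- rnbinom(n, mu = 1, size = 1)
  nul <- build_null_asymptotic(n, tie_profile(y))
  r0 <- tau_star_stat(x, y)
  p0 <- pvalue(r0, nul)
  expect_gt(p0, 0)
  expect_lte(p0, 1)
  # monotone nonincreasing in the observed statistic
  ts <- seq(-0.5, 5, length.out = 30)
  expect_true(all(diff(vapply(ts, nul$tail_fn, numeric(1))) <= 0))
  # monotone-in-pseudotime gene at n = 10000: far-right tail
  nul_big <- build_null_asymptotic(10000, tie_profile(y))
  expect_lt(nul_big$tail_fn(10000 * 2 / 3), 1e-6)
  # permutation p-value: add-one estimator never returns 0
  pn <- build_null_permutation(x, y, B = 199, seed = 3)
  pp <- pvalue(r0, pn)
  expect_gte(pp, 1 / 200)
  expect_lte(pp, 1)
  # incompatible n is caught
  expect_error(pvalue(tau_star_stat(x[1:100], y[1:100]), nul), "n = ")
})

test_that("margin kernel annihilates constants (weighted row sums vanish)", {
  p <- c(0.5, 0.3, 0.15, 0.05)
  phi <- pseudotau:::phiA_discrete(p)
  expect_equal(max(abs(phi %*% p)), 0, tolerance = 1e-12)
  # symmetric kernel
  expect_equal(phi, t(phi), tolerance = 1e-12)
})

test_that("binary-margin null law reduces to the closed-form single coefficient", {
  # for Bernoulli(q) margins the phiA operator has a single nonzero
  # eigenvalue; for q = 1/2 x 1/2 the product coefficient is exactly 1/4,
  # verifiable by hand from the 2x2 kernel matrix
  nul <- build_null_asymptotic(500, c(0.5, 0.5),
                               x_tie_profile = c(0.5, 0.5))
  expect_length(nul$coefficients, 1L)
  expect_equal(nul$coefficients, 0.25, tolerance = 1e-10)
})
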