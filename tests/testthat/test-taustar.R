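test_that("sign kernel matches its defining arithmetic on canonical quartets", {
  expect_identical(sign_kernel(1, 3, 2, 4), 1L)
  expect_identical(sign_kernel(1, 2, 3, 4), -1L)
  expect_identical(sign_kernel(5, 5, 5, 5), 0L)
  expect_identical(sign_kernel(1, 3, 4, 2), 0L)
  # vectorized and equal to the oracle kernel on random quartets
  set.seed(1)
  z <- matrix(sample(0:3, 400, replace = TRUE), ncol = 4)
  got <- sign_kernel(z[, 1], z[, 2], z[, 3], z[, 4])
  expect_identical(got, apply(z, 1, oracle_kernel))
  expect_error(sign_kernel(1, NA, 2, 3), "finite")
})

test_that("brute-force tau* reproduces hand-derivable identities", {
  expect_equal(tau_star_brute(1:4, 1:4), 2 / 3, tolerance = 1e-12)
  expect_equal(tau_star_brute(1:5, 5:1), 2 / 3, tolerance = 1e-12)
  expect_equal(tau_star_brute(1:5, rep(7, 5)), 0)
  expect_error(tau_star_brute(1:3, 1:3), "fewer than 4")
  expect_error(tau_star_brute(1:5, 1:4), "lengths")
})

test_that("pairwise and fast tiers equal the independent R oracle on tied data", {
  set.seed(42)
  for (rep in 1:60) {
    inst <- random_tied_instance(sample(4:6, 1))
    ref <- oracle_tau_star(inst$x, inst$y)
    expect_equal(tau_star_brute(inst$x, inst$y), ref, tolerance = 1e-12)
    expect_equal(tau_star_pairwise(inst$x, inst$y), ref, tolerance = 1e-12)
    expect_equal(suppressMessages(tau_star_fast(inst$x, inst$y)), ref,
                 tolerance = 1e-12)
  }
  # a few larger ones against the C++ brute tier
  for (rep in 1:10) {
    n <- 30
    x <- sample(0:9, n, replace = TRUE)
    y <- rnbinom(n, mu = 1, size = 1)
    ref <- tau_star_brute(x, y)
    expect_equal(tau_star_pairwise(x, y), ref, tolerance = 1e-10)
  }
})

test_that("fast path delegates to the pairwise tier when pseudotime is tied", {
  x <- c(1, 1, 2, 3, 4)
  y <- c(0, 1, 0, 2, 0)
  expect_message(got <- tau_star_fast(x, y), "pairwise")
  expect_equal(got, tau_star_brute(x, y), tolerance = 1e-12)
})

test_that("tau* is symmetric, rank-invariant and permutation-equivariant", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    x <- runif(n)
    y <- rnbinom(n, mu = 2, size = 1)
    ref <- tau_star_pairwise(x, y)
    # symmetry in the two margins
    expect_equal(tau_star_pairwise(y, x), ref, tolerance = 1e-12)
    # strictly increasing transforms change nothing
    expect_equal(tau_star_pairwise(exp(3 * x), y), ref, tolerance = 1e-12)
    expect_equal(suppressMessages(tau_star_fast(x, y^3 + 2 * y)), ref,
                 tolerance = 1e-12)
    # joint permutation of cells changes nothing
    pp <- sample(n)
    expect_equal(tau_star_pairwise(x[pp], y[pp]), ref, tolerance = 1e-12)
    # bound under tie-free pseudotime
    expect_lte(abs(ref), 2 / 3 + 1e-12)
  }
})

test_that("monotone dependence attains tau* = 2/3 exactly at any n", {
  for (n in c(4, 10, 100)) {
    x <- seq_len(n) / n
    expect_equal(tau_star_fast(x, rank(x)), 2 / 3, tolerance = 1e-12)
  }
  expect_equal(tau_star_fast(seq(0.1, 1, by = 0.1), rank(seq(0.1, 1, by = 0.1))),
               2 / 3, tolerance = 1e-12)
})

test_that("tie profile counts levels and multiplicities", {
  tp <- tie_profile(c(0, 0, 0, 2, 2, 7))
  expect_equal(tp$M, 3L)
  expect_equal(tp$level_values, c(0, 2, 7))
  expect_equal(tp$level_counts, c(3L, 2L, 1L))
  expect_equal(sum(tp$level_probs), 1)
  expect_equal(tie_profile(rep(3, 9))$M, 1L)
  expect_equal(tie_profile(rnorm(25))$M, 25L)
  expect_error(tie_profile(numeric(0)), "empty")
})

test_that("tau_star_stat records algorithm, scaled statistic and tie profile", {
  set.seed(3)
  x <- runif(50)
  y <- rnbinom(50, mu = 1, size = 1)
  r <- tau_star_stat(x, y, gene_id = "g1")
  expect_s3_class(r, "tau_star_result")
  expect_equal(r$scaled_stat, 50 * r$tau_star)
  expect_equal(r$algorithm_used, "fast")
  expect_equal(r$tau_star, tau_star_brute(x, y), tolerance = 1e-10)
  r2 <- tau_star_stat(c(1, 1, 2, 3, 4), y[1:5])
  expect_equal(r2$algorithm_used, "pairwise")
})
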