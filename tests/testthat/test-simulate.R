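test_that("generators are reproducible from their seed and record their truth", {
  d1 <- simulate_null_dataset(200, 50, seed = 3)
  d2 <- simulate_null_dataset(200, 50, seed = 3)
  expect_identical(as.matrix(d1$counts), as.matrix(d2$counts))
  expect_identical(d1$pseudotime, d2$pseudotime)
  expect_false(any(d1$is_de))
  e1 <- simulate_de_dataset(150, 40, seed = 5)
  e2 <- simulate_de_dataset(150, 40, seed = 5)
  expect_identical(as.matrix(e1$counts), as.matrix(e2$counts))
  expect_identical(e1$effect_size, e2$effect_size)
})

test_that("the DE fraction is honored exactly", {
  d <- simulate_de_dataset(100, 2000, frac_de = 0.2, seed = 1)
  expect_equal(sum(d$is_de), 400L)
  expect_true(all(d$effect_size[d$is_de] > 0))
  expect_true(all(d$effect_size[!d$is_de] == 0))
  expect_error(simulate_de_dataset(100, 100, frac_de = 0), "frac_de")
})

test_that("default null genes live in the sparse few-levels regime", {
  d <- simulate_null_dataset(1000, 300, seed = 8)
  M <- apply(as.matrix(d$counts), 2, function(y) length(unique(y)))
  expect_lte(median(M), 15)
  # heavier zero inflation with low means gives even fewer levels
  d2 <- simulate_null_dataset(1000, 100, nb_mean_range = c(0.05, 0.3),
                              zero_inflation = 0.9, seed = 8)
  M2 <- apply(as.matrix(d2$counts), 2, function(y) length(unique(y)))
  expect_lte(median(M2), 5)
})

test_that("null genes are independent of pseudotime by construction", {
  d <- simulate_null_dataset(500, 400, seed = 2)
  cors <- apply(as.matrix(d$counts), 2, function(y)
    if (sd(y) == 0) 0 else cor(y, d$pseudotime$pseudotime))
  expect_lt(abs(mean(cors)), 3 / sqrt(500 * 400 / 2))
  expect_lt(max(abs(cors)), 0.25)
})

test_that("zero effect size collapses the DE generator onto flat trends", {
  d <- simulate_de_dataset(300, 60, effect_size_range = c(0, 0), seed = 4)
  cors <- apply(as.matrix(d$counts[, d$is_de]), 2, function(y)
    if (sd(y) == 0) 0 else cor(y, d$pseudotime$pseudotime))
  expect_lt(max(abs(cors)), 0.25)
})

test_that("a strong monotone DE gene is detected against a permutation oracle", {
  set.seed(6)
  n <- 1000
  t <- runif(n)
  y <- rnbinom(n, mu = exp(0.2 + 2.5 * (t - 0.5)), size = 1)
  pn <- build_null_permutation(t, y, B = 2000, seed = 10)
  p <- pvalue(tau_star_stat(t, y), pn)
  expect_lt(p, 0.001)
})

test_that("calibration report detects uniform and degenerate p-value sets", {
  set.seed(12)
  ok <- 0
  for (s in 1:10) {
    cal <- evaluate_calibration(runif(10000))
    if (cal$ks_pvalue > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 9)
  bad <- evaluate_calibration(rep(0.5, 500))
  expect_lt(bad$ks_pvalue, 1e-10)
  expect_true(all(diff(bad$qq_points$expected) >= 0))
  expect_error(evaluate_calibration(numeric(0)), "no p-values")
})

test_that("power/FDR report counts calls against ground truth", {
  tab <- data.frame(gene_id = paste0("g", 1:10),
                    qvalue = c(0.01, 0.2, 0.03, NA, 0.5, 0.04, 0.9, 0.02,
                               0.06, NA))
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE)
  rep_ <- evaluate_power_fdr(tab, truth, fdr_level = 0.05)
  expect_equal(rep_$n_called, 4L)
  expect_equal(rep_$true_positives, 3L)
  expect_equal(rep_$false_positives, 1L)
  expect_equal(rep_$empirical_fdr, 0.25)
  expect_equal(rep_$empirical_power, 3 / 5)
  none <- evaluate_power_fdr(tab, truth, fdr_level = 0.001)
  expect_equal(none$empirical_fdr, 0)
  expect_equal(none$empirical_power, 0)
  expect_error(evaluate_power_fdr(tab, truth[1:5]), "labels")
})
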