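# Trajectory-structured synthetic scRNA-seq generator.
#
# Emulates the statistical features of real trajectory data that the test
# must handle -- sparse negative-binomial counts with gene-specific mean and
# dispersion, heavy zero inflation (few unique values per gene), and for DE
# genes a log-mean varying smoothly with pseudotime -- without modelling
# library-size variation, batch structure, or pseudotime-inference noise.

sim_check_range <- function(r, name, positive = TRUE) {
  if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] ||
      (positive && r[1] <= 0))
    stop("invalid ", name, ": must be a finite ",
         if (positive) "positive " else "", "pair (lo, hi)")
  r
}

rdunif <- function(n, r) r[1] + (r[2] - r[1]) * stats::runif(n)
rlogunif <- function(n, r) exp(rdunif(n, log(r)))

#' Simulate null genes independent of pseudotime
#'
#' Generates a cells-by-genes count matrix in which every gene is drawn from
#' a zero-inflated negative binomial, fully independent of the
#' Uniform(0, 1) pseudotime: the ground truth for calibration studies.
#' Gene means are log-uniform over `nb_mean_range` and dispersions (NB
#' `size`) uniform over `nb_dispersion_range`; the defaults give the sparse
#' regime typical of scRNA-seq (median gene with at most ~15 unique values
#' at 1000 cells).
#'
#' @param n_cells,n_genes dimensions of the simulated matrix.
#' @param nb_mean_range log-uniform sampling range for gene mean expression.
#' @param nb_dispersion_range uniform sampling range for the NB size
#'   (inverse-dispersion) parameter; smaller = more overdispersed.
#' @param zero_inflation probability in \[0, 1) of forcing any count to zero,
#'   on top of NB sampling zeros.
#' @param seed integer seed; the dataset is reproducible from
#'   `generator_params`.
#' @return object of class `synthetic_dataset`: list with `counts` (sparse
#'   dgCMatrix, cells x genes), `pseudotime` (data.frame `cell_id`,
#'   `pseudotime`), `is_de` (logical per gene), `generator_params`.
#' @export
simulate_null_dataset <- function(n_cells, n_genes,
                                  nb_mean_range = c(0.1, 2),
                                  nb_dispersion_range = c(0.5, 2),
                                  zero_inflation = 0.2,
                                  seed = 1L) {
  if (n_cells < 4 || n_genes < 1) stop("invalid dimensions")
  sim_check_range(nb_mean_range, "nb_mean_range")
  sim_check_range(nb_dispersion_range, "nb_dispersion_range")
  if (zero_inflation < 0 || zero_inflation >= 1)
    stop("zero_inflation must be in [0, 1)")
  params <- list(generator = "null", n_cells = n_cells, n_genes = n_genes,
                 nb_mean_range = nb_mean_range,
                 nb_dispersion_range = nb_dispersion_range,
                 zero_inflation = zero_inflation, seed = seed)
  simulate_zinb(params, frac_de = 0, effect_shapes = character(),
                effect_size_range = c(0, 0))
}

#' Simulate a trajectory dataset with known differentially expressed genes
#'
#' A fraction `frac_de` of genes follow a smooth pseudotime trend in their
#' log-mean, \eqn{\log \mu_g(t) = \log \mu_{0g} + \gamma_g s_g(t)}, with the
#' trend shape \eqn{s_g} drawn uniformly from `effect_shapes`
#' (monotone, unimodal bump, or sigmoidal switch, each mapped to \[0, 1\])
#' and signed amplitude \eqn{|\gamma_g|} uniform over `effect_size_range`.
#' The remaining genes are null exactly as in [simulate_null_dataset()].
#'
#' @inheritParams simulate_null_dataset
#' @param frac_de fraction of genes carrying a pseudotime trend, in (0, 1);
#'   `round(frac_de * n_genes)` genes (the first ones) are flagged DE.
#' @param effect_shapes subset of `c("monotone", "unimodal", "sigmoidal")`.
#' @param effect_size_range range for the log-scale trend amplitude.
#' @return a `synthetic_dataset` (see [simulate_null_dataset()]); `is_de`
#'   records the ground truth.
#' @export
simulate_de_dataset <- function(n_cells, n_genes = 2000, frac_de = 0.2,
                                effect_shapes = c("monotone", "unimodal",
                                                  "sigmoidal"),
                                effect_size_range = c(0.5, 2.5),
                                nb_dispersion_range = c(0.5, 2),
                                nb_mean_range = c(0.1, 2),
                                zero_inflation = 0.2,
                                seed = 1L) {
  if (n_cells < 4 || n_genes < 1) stop("invalid dimensions")
  if (frac_de <= 0 || frac_de >= 1) stop("frac_de must be in (0, 1)")
  effect_shapes <- match.arg(effect_shapes, several.ok = TRUE)
  sim_check_range(nb_mean_range, "nb_mean_range")
  sim_check_range(nb_dispersion_range, "nb_dispersion_range")
  sim_check_range(effect_size_range, "effect_size_range", positive = FALSE)
  params <- list(generator = "de", n_cells = n_cells, n_genes = n_genes,
                 nb_mean_range = nb_mean_range,
                 nb_dispersion_range = nb_dispersion_range,
                 zero_inflation = zero_inflation, seed = seed,
                 frac_de = frac_de, effect_shapes = effect_shapes,
                 effect_size_range = effect_size_range)
  simulate_zinb(params, frac_de = frac_de, effect_shapes = effect_shapes,
                effect_size_range = effect_size_range)
}

# shared generator core
simulate_zinb <- function(params, frac_de, effect_shapes, effect_size_range) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  n <- params$n_cells
  p <- params$n_genes
  t <- stats::runif(n)
  n_de <- if (frac_de > 0) round(frac_de * p) else 0L
  is_de <- seq_len(p) <= n_de

  mu0 <- rlogunif(p, params$nb_mean_range)
  size <- rdunif(p, params$nb_dispersion_range)
  effect_size <- rep(0, p)
  effect_shape <- rep(NA_character_, p)
  counts <- matrix(0L, n, p)
  for (g in seq_len(p)) {
    mu <- rep(mu0[g], n)
    if (is_de[g]) {
      shape <- sample(effect_shapes, 1)
      gamma <- sample(c(-1, 1), 1) * rdunif(1, effect_size_range)
      effect_size[g] <- abs(gamma)
      effect_shape[g] <- shape
      s <- trend_shape(t, shape)
      # center the trend so the gene keeps its baseline scale
      mu <- mu0[g] * exp(gamma * (s - mean(s)))
    }
    cnt <- stats::rnbinom(n, mu = mu, size = size[g])
    if (params$zero_inflation > 0)
      cnt[stats::runif(n) < params$zero_inflation] <- 0L
    counts[, g] <- cnt
  }
  dimnames(counts) <- list(sprintf("cell%0*d", nchar(n), seq_len(n)),
                           sprintf("gene%0*d", nchar(p), seq_len(p)))
  structure(
    list(counts = Matrix::Matrix(counts, sparse = TRUE),
         pseudotime = data.frame(cell_id = rownames(counts), pseudotime = t,
                                 stringsAsFactors = FALSE),
         is_de = is_de, effect_size = effect_size,
         effect_shape = effect_shape, generator_params = params),
    class = "synthetic_dataset"
  )
}

# smooth trend shapes on [0,1], each mapped into [0,1]
trend_shape <- function(t, shape) {
  switch(shape,
         monotone = t,
         unimodal = {
           c0 <- stats::runif(1, 0.3, 0.7)
           w <- stats::runif(1, 0.1, 0.25)
           exp(-(t - c0)^2 / (2 * w^2))
         },
         sigmoidal = {
           c0 <- stats::runif(1, 0.25, 0.75)
           k <- stats::runif(1, 8, 20)
           stats::plogis(k * (t - c0))
         },
         stop("unknown trend shape: ", shape))
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic trajectory dataset:", nrow(x$counts), "cells x",
      ncol(x$counts), "genes;", sum(x$is_de), "DE genes (",
      x$generator_params$generator, "generator, seed",
      x$generator_params$seed, ")\n")
  invisible(x)
}
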