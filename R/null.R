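# Asymptotic null law of the scaled statistic n * tau*_n under independence.
#
# tau*_n is a rank-based U-statistic of order 4 whose first projection
# vanishes under independence, so n * tau*_n converges to a centered
# quadratic form in independent standard normals (second-order Gaussian
# chaos). Writing the quartet kernel as a difference of split-separation
# indicators, the conditional expectation with two points fixed factorizes
# over the margins into a single symmetric kernel per margin,
#   phiA(s, t) = P(the (s,Z)|(t,Z') split is strictly separated)
#              - P(the (s,t)|(Z,Z') split is strictly separated),
# and the second projection of the symmetrized kernel is
#   h2 = (2/3) * phiA_x(x1, x2) * phiA_y(y1, y2).
# Degenerate U-statistic theory then gives
#   n * tau*_n  -->d  4 * sum_{u,v} alpha_u beta_v (Z_uv^2 - 1),
# with alpha_u, beta_v the eigenvalues of the phiA integral operator on each
# margin. A margin with M levels contributes an exact M x M matrix; a
# continuous (tie-free) margin is rank-equivalent to Uniform(0,1) and is
# handled by Nystrom quadrature. Upper-tail probabilities of the quadratic
# form are computed by Gil-Pelaez characteristic-function inversion, with a
# Lugannani-Rice saddlepoint approximation taking over deep in the tail.

# phiA kernel matrix for a discrete margin with level probabilities p
# (levels in ascending order); depends on the margin only through p.
phiA_discrete <- function(p) {
  M <- length(p)
  F1 <- cumsum(p)            # P(Z <= v_l)
  G <- F1 - p                # P(Z < v_l)
  S <- 1 - F1                # P(Z > v_l)
  cs <- cumsum(p * S)        # prefix sums of p_l * S_l
  lo <- pmin(row(diag(M)), col(diag(M)))
  hi <- pmax(row(diag(M)), col(diag(M)))
  # W(lo,hi) = P(mixed split separated) for fixed values v_lo < v_hi
  W <- F1[lo] * S[lo] + (cs[pmax(hi - 1, 1)] - cs[lo]) * (hi - 1 >= lo + 1)
  W[lo == hi] <- 0
  W - (S[hi]^2 + G[lo]^2)
}

# Eigenvalues of the phiA operator for a discrete margin (tie profile).
margin_eigs_discrete <- function(p) {
  B <- phiA_discrete(p) * tcrossprod(sqrt(p))
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  ev[abs(ev) > 1e-14]
}

# Eigenvalues for a continuous (tie-free) margin: Uniform(0,1) by rank
# invariance, Nystrom midpoint quadrature with K nodes. Cached per K.
continuous_eig_cache <- new.env(parent = emptyenv())
margin_eigs_continuous <- function(K = 256L) {
  key <- as.character(K)
  if (!is.null(continuous_eig_cache[[key]])) return(continuous_eig_cache[[key]])
  s <- (seq_len(K) - 0.5) / K
  lo <- outer(s, s, pmin)
  hi <- outer(s, s, pmax)
  W <- lo * (1 - lo) + (hi - lo) - (hi^2 - lo^2) / 2
  phi <- W - ((1 - hi)^2 + lo^2)
  B <- phi / K
  # enforce exact annihilation of constants (quadrature error otherwise)
  J <- diag(K) - 1 / K
  B <- J %*% B %*% J
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[abs(ev) > 1e-12]
  continuous_eig_cache[[key]] <- ev
  ev
}

#' Asymptotic null distribution of the scaled tau-star statistic
#'
#' Builds the limiting null law of \eqn{n\,\tau^*_n} under independence,
#' adapted to the tie structure of both margins: a centered quadratic form
#' \eqn{4\sum_{u,v}\alpha_u\beta_v(Z_{uv}^2-1)} in independent standard
#' normals, whose coefficients are products of eigenvalues of a
#' per-margin kernel operator derived from the quartet sign kernel. The
#' returned object evaluates upper-tail probabilities deterministically
#' (numerical characteristic-function inversion; saddlepoint in the far
#' tail).
#'
#' @param n sample size (number of cells), at least 4.
#' @param tie_profile `tie_profile` of the expression margin (or a bare
#'   vector of level probabilities).
#' @param x_tie_profile `tie_profile` of the pseudotime margin, or `NULL`
#'   (the default) for a tie-free margin, treated as continuous.
#' @return object of class `taustar_null`: list with `kind`, `n`,
#'   `coefficients` (the products \eqn{4\alpha_u\beta_v}), `support_summary`
#'   (mean 0 and the limit variance), and `tail_fn(t)` returning
#'   \eqn{P(\mathrm{limit} \ge t)}.
#' @export
build_null_asymptotic <- function(n, tie_profile, x_tie_profile = NULL) {
  if (n < 4) stop("null distribution requires n >= 4")
  py <- if (inherits(tie_profile, "tie_profile")) tie_profile$level_probs
        else as.numeric(tie_profile)
  if (length(py) < 2)
    stop("statistic is identically zero for a constant margin (M = 1); ",
         "no test possible")
  if (abs(sum(py) - 1) > 1e-8) stop("level probabilities must sum to 1")
  beta <- margin_eigs_discrete(py)
  if (is.null(x_tie_profile)) {
    alpha <- margin_eigs_continuous()
    kind <- "asymptotic_continuous"
  } else {
    px <- if (inherits(x_tie_profile, "tie_profile"))
      x_tie_profile$level_probs else as.numeric(x_tie_profile)
    if (length(px) < 2)
      stop("statistic is identically zero for a constant margin (M = 1); ",
           "no test possible")
    alpha <- margin_eigs_discrete(px)
    kind <- "asymptotic_discrete"
  }
  co <- as.numeric(4 * outer(alpha, beta))
  co <- co[abs(co) > max(abs(co)) * 1e-9]
  co <- co[order(abs(co), decreasing = TRUE)]
  # keep the dominant coefficients exactly; the many small remaining chaos
  # terms are jointly approximated by their Gaussian limit (their summed
  # variance is a tiny fraction of the total)
  keep <- seq_len(min(length(co), 100L))
  big <- co[keep]
  s2rest <- 2 * sum(co[-keep]^2)
  structure(
    list(kind = kind, n = n,
         tie_profile = if (inherits(tie_profile, "tie_profile")) tie_profile else NULL,
         coefficients = co,
         support_summary = c(mean = 0, variance = 2 * sum(co^2)),
         tail_fn = function(t) qform_upper_tail(t, big, s2rest)),
    class = "taustar_null"
  )
}

#' @export
print.taustar_null <- function(x, ...) {
  cat("tau* null distribution [", x$kind, "], n =", x$n, "\n")
  cat("  quadratic form with", length(x$coefficients),
      "coefficients; limit sd =",
      format(sqrt(x$support_summary["variance"]), digits = 4), "\n")
  invisible(x)
}

# P(sum_k c_k (Z_k^2 - 1) + N(0, s2rest) >= t) by Gil-Pelaez inversion:
#   p = 1/2 + (1/pi) Int_0^inf sin(theta(u)) / (u rho(u)) du,
#   theta(u) = sum_k [atan(2 c_k u)/2 - c_k u] - u t,
#   rho(u)   = prod_k (1 + 4 c_k^2 u^2)^{1/4} * exp(s2rest u^2 / 2).
# Below ~1e-4 the integral is cancellation-limited and the saddlepoint
# (Lugannani-Rice) value is used instead.
qform_upper_tail <- function(t, coef, s2rest = 0) {
  vapply(t, function(ti) qform_upper_tail1(ti, coef, s2rest), numeric(1))
}

qform_upper_tail1 <- function(t, coef, s2rest = 0) {
  if (!is.finite(t)) return(if (t > 0) 0 else 1)
  # far beyond the bulk the oscillatory integral is pure cancellation noise;
  # go straight to the saddlepoint there
  sd_tot <- sqrt(2 * sum(coef^2) + s2rest)
  if (t > 8 * sd_tot) {
    sp <- qform_saddlepoint(t, coef, s2rest)
    if (!is.na(sp)) return(sp)
  }
  integrand <- function(u) {
    th <- colSums(0.5 * atan(2 * outer(coef, u)) - coef %o% u) - u * t
    lr <- colSums(0.25 * log1p(4 * outer(coef^2, u^2))) + s2rest * u^2 / 2
    ifelse(u == 0, -t, sin(th) * exp(-lr) / u)
  }
  p <- tryCatch({
    ii <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-9, abs.tol = 1e-11,
                           subdivisions = 2000L, stop.on.error = FALSE)
    0.5 + ii$value / pi
  }, error = function(e) NA_real_)
  if (is.na(p) || p < 1e-4) {
    sp <- qform_saddlepoint(t, coef, s2rest)
    if (!is.na(sp)) return(sp)
    if (is.na(p)) stop("tail probability evaluation failed at t = ", t)
  }
  min(max(p, 0), 1)
}

# Lugannani-Rice saddlepoint for the upper tail of
# sum c_k (Z_k^2 - 1) + N(0, s2rest), valid for t above the mean (t > 0);
# cgf K(s) = sum [-log(1-2 c s)/2 - c s] + s2rest s^2 / 2.
qform_saddlepoint <- function(t, coef, s2rest = 0) {
  cmax <- max(coef)
  if (t <= 0 || cmax <= 0) return(NA_real_)
  smax <- 1 / (2 * cmax)
  Kp <- function(s) sum(coef / (1 - 2 * coef * s) - coef) + s2rest * s
  f <- function(s) Kp(s) - t
  hi <- smax * (1 - 1e-9)
  if (f(hi) < 0) return(1e-300)                  # beyond representable tail
  s <- stats::uniroot(f, c(1e-14, hi), tol = 1e-14)$root
  K <- sum(-0.5 * log1p(-2 * coef * s) - coef * s) + s2rest * s^2 / 2
  K2 <- sum(2 * coef^2 / (1 - 2 * coef * s)^2) + s2rest
  w <- sign(s) * sqrt(2 * (s * t - K))
  v <- s * sqrt(K2)
  if (w == 0) return(NA_real_)
  p <- stats::pnorm(w, lower.tail = FALSE) + stats::dnorm(w) * (1 / v - 1 / w)
  min(max(p, 1e-300), 1)
}

#' Permutation null for tau-star
#'
#' Draws the permutation distribution of \eqn{\tau^*_n} by repeatedly
#' permuting the expression vector against the fixed pseudotime vector.
#' Serves as a finite-sample validation oracle for the asymptotic null and
#' as a fallback test when the asymptotic approximation is in doubt.
#'
#' @param x pseudotime vector.
#' @param y expression vector.
#' @param B number of permutation replicates (>= 100 recommended).
#' @param seed integer seed; identical seeds give identical draws.
#' @return object of class `taustar_perm_null`: list with `draws` (B values
#'   of \eqn{\tau^*_n}), `B`, `seed`, `n`.
#' @export
build_null_permutation <- function(x, y, B, seed) {
  v <- check_tau_inputs(x, y)
  if (B < 1) stop("B must be >= 1")
  n <- length(v$x)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (!anyDuplicated(v$x)) {
    ord <- order(v$x)
    code <- match(v$y, sort(unique(v$y)))[ord]
    draws <- cpp_perm_null_fast(code, max(code), as.integer(B))
  } else {
    draws <- vapply(seq_len(B), function(b)
      cpp_tau_pairwise(v$x, sample(v$y)), numeric(1))
  }
  structure(list(draws = draws, B = as.integer(B), seed = seed, n = n),
            class = "taustar_perm_null")
}

#' P-value for a tau-star test result
#'
#' One-sided upper-tail p-value: the population \eqn{\tau^*} is nonnegative
#' and equals zero exactly at independence, so evidence against independence
#' accumulates only in the right tail of the null law of the scaled
#' statistic. Against a permutation null the add-one estimator
#' \eqn{(1 + \#\{draws \ge observed\})/(B+1)} is used, which never returns 0.
#'
#' @param result a `tau_star_result` from [tau_star_stat()].
#' @param null a `taustar_null` from [build_null_asymptotic()] or a
#'   `taustar_perm_null` from [build_null_permutation()].
#' @return p-value in (0, 1\].
#' @export
pvalue <- function(result, null) {
  if (!inherits(result, "tau_star_result"))
    stop("result must be a tau_star_result")
  if (inherits(null, "taustar_null")) {
    if (null$n != result$n)
      stop("null distribution was built for n = ", null$n,
           " but the result has n = ", result$n)
    return(null$tail_fn(result$scaled_stat))
  }
  if (inherits(null, "taustar_perm_null")) {
    if (null$n != result$n)
      stop("permutation null was built for n = ", null$n,
           " but the result has n = ", result$n)
    return((1 + sum(null$draws >= result$tau_star)) / (null$B + 1))
  }
  stop("null must be a taustar_null or taustar_perm_null")
}
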