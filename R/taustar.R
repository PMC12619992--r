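#' Quartet sign kernel
#'
#' The kernel \eqn{a(z_1,z_2,z_3,z_4) = \mathrm{sign}(|z_1-z_2|+|z_3-z_4|
#' -|z_1-z_3|-|z_2-z_4|)} classifying four points on the line: +1 when the
#' pairs \{z1,z3\} and \{z2,z4\} are strictly separated, -1 when \{z1,z2\} and
#' \{z3,z4\} are, and 0 otherwise (in particular under ties straddling the
#' relevant boundary). It is the building block of the Bergsma-Dassios sign
#' covariance: the tau-star U-statistic averages the product of the x- and
#' y-kernel over all quadruples of distinct cells.
#'
#' @param z1,z2,z3,z4 numeric vectors (recycled to common length); all values
#'   must be finite.
#' @return integer vector in \{-1, 0, 1\}.
#' @examples
#' sign_kernel(1, 3, 2, 4)  # +1
#' sign_kernel(1, 2, 3, 4)  # -1
#' @export
sign_kernel <- function(z1, z2, z3, z4) {
  args <- lapply(list(z1, z2, z3, z4), as.numeric)
  if (!all(vapply(args, function(a) all(is.finite(a)), logical(1))))
    stop("sign_kernel: all arguments must be finite numeric values")
  n <- max(lengths(args))
  args <- lapply(args, rep_len, n)
  cpp_sign_kernel(args[[1]], args[[2]], args[[3]], args[[4]])
}

check_tau_inputs <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("pseudotime and expression vectors have different lengths (",
         length(x), " vs ", length(y), ")")
  if (length(x) < 4L)
    stop("tau* is undefined for fewer than 4 cells (got n = ", length(x), ")")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("tau* inputs must be finite")
  list(x = x, y = y)
}

#' Tau-star estimators of the Bergsma-Dassios sign covariance
#'
#' Three exact computations of the U-statistic
#' \deqn{\tau^*_n = \frac{(n-4)!}{n!} \sum_{i,j,k,l\ \mathrm{distinct}}
#'   a(x_i,x_j,x_k,x_l)\, a(y_i,y_j,y_k,y_l),}
#' which estimates the Bergsma-Dassios sign covariance \eqn{\tau^*}, a
#' dependence measure that is zero if and only if the two variables are
#' independent. All three return identical values (up to summation-order
#' rounding, at most ~1e-12); they differ only in cost:
#'
#' * `tau_star_brute()` enumerates all ordered quadruples directly from the
#'   defining formula; O(n^4), the ground-truth oracle.
#' * `tau_star_pairwise()` counts concordant and discordant quadruples through
#'   per-pair dominance counts with a Fenwick tree; O(n^2 log n), exact under
#'   ties in either margin.
#' * `tau_star_fast()` is the production path: after sorting cells by
#'   pseudotime, the core counting step costs O(M n), where M is the number of
#'   unique expression values (small for sparse scRNA-seq genes). It requires
#'   strictly distinct pseudotime values; when ties are present it delegates to
#'   `tau_star_pairwise()` with a notice rather than approximate.
#'
#' @param x numeric vector of per-cell pseudotime.
#' @param y numeric vector of per-cell expression for one gene, same length.
#' @return the value of \eqn{\tau^*_n}, a number in \[-1, 1\] (at most 2/3 when
#'   the pseudotime margin is tie-free).
#' @examples
#' tau_star_fast(1:10, (1:10)^2)  # monotone dependence: 2/3
#' tau_star_fast(1:10, rep(1, 10))  # constant gene: 0
#' @export
tau_star_brute <- function(x, y) {
  v <- check_tau_inputs(x, y)
  cpp_tau_brute(v$x, v$y)
}

#' @rdname tau_star_brute
#' @export
tau_star_pairwise <- function(x, y) {
  v <- check_tau_inputs(x, y)
  cpp_tau_pairwise(v$x, v$y)
}

#' @rdname tau_star_brute
#' @export
tau_star_fast <- function(x, y) {
  v <- check_tau_inputs(x, y)
  if (anyDuplicated(v$x)) {
    message("tau_star_fast: pseudotime has tied values; ",
            "delegating to the exact O(n^2 log n) pairwise algorithm")
    return(cpp_tau_pairwise(v$x, v$y))
  }
  ord <- order(v$x)
  code <- match(v$y, sort(unique(v$y)))[ord]
  cpp_tau_fast_sorted(code, max(code))
}

#' Tie profile of an expression vector
#'
#' Summarizes the unique values (levels) a gene takes and their
#' multiplicities. The number of levels M drives both the fast algorithm's
#' O(Mn) core step and the discrete-margin asymptotic null.
#'
#' @param y numeric vector (nonempty).
#' @return an object of class `tie_profile`: list with `n`, `M`,
#'   `level_values` (sorted unique values), `level_counts`, `level_probs`.
#' @examples
#' tie_profile(c(0, 0, 0, 2, 2, 7))
#' @export
tie_profile <- function(y) {
  y <- as.numeric(y)
  if (length(y) == 0L) stop("tie_profile: empty input")
  if (!all(is.finite(y))) stop("tie_profile: values must be finite")
  lv <- sort(unique(y))
  cnt <- tabulate(match(y, lv), nbins = length(lv))
  structure(
    list(n = length(y), M = length(lv), level_values = lv,
         level_counts = cnt, level_probs = cnt / length(y)),
    class = "tie_profile"
  )
}

#' @export
print.tie_profile <- function(x, ...) {
  cat("Tie profile: n =", x$n, ", M =", x$M, "unique levels\n")
  show <- min(x$M, 8L)
  cat("  levels:", paste(signif(x$level_values[seq_len(show)], 4),
                         collapse = " "),
      if (x$M > show) "...\n" else "\n")
  invisible(x)
}

#' Compute tau-star with metadata for one gene
#'
#' Convenience wrapper returning the statistic together with the scaled
#' statistic \eqn{n\,\tau^*_n} (the quantity with a nondegenerate limit under
#' independence), the expression tie profile, and which algorithm ran.
#'
#' @param x per-cell pseudotime vector.
#' @param y per-cell expression vector.
#' @param gene_id optional gene identifier carried through.
#' @param method `"fast"` (default), `"pairwise"`, or `"brute"`.
#' @return object of class `tau_star_result` with fields `gene_id`,
#'   `tau_star`, `scaled_stat`, `n`, `tie_profile`, `algorithm_used`.
#' @export
tau_star_stat <- function(x, y, gene_id = NA_character_,
                          method = c("fast", "pairwise", "brute")) {
  method <- match.arg(method)
  v <- check_tau_inputs(x, y)
  algo <- method
  if (method == "fast" && anyDuplicated(v$x)) algo <- "pairwise"
  ts <- switch(method,
               fast = tau_star_fast(v$x, v$y),
               pairwise = tau_star_pairwise(v$x, v$y),
               brute = tau_star_brute(v$x, v$y))
  structure(
    list(gene_id = gene_id, tau_star = ts, scaled_stat = length(v$x) * ts,
         n = length(v$x), tie_profile = tie_profile(v$y),
         algorithm_used = algo),
    class = "tau_star_result"
  )
}

#' @export
print.tau_star_result <- function(x, ...) {
  cat("tau* =", format(x$tau_star, digits = 6),
      " (n =", x$n, ", n*tau* =", format(x$scaled_stat, digits = 6),
      ", M =", x$tie_profile$M, ", algorithm =", x$algorithm_used, ")\n")
  invisible(x)
}
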