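# Independent pure-R brute-force oracle for tau*_n: averages the product of
# quartet kernels over all quadruples, with the kernel evaluated through the
# exact split-separation characterization (the naive absolute-difference
# formula hits an exact mathematical zero for the two unseparated pairings,
# which floating-point rounding otherwise turns into spurious +/-1).

oracle_kernel <- function(z) {
  (max(z[1], z[3]) < min(z[2], z[4]) || max(z[2], z[4]) < min(z[1], z[3])) -
  (max(z[1], z[2]) < min(z[3], z[4]) || max(z[3], z[4]) < min(z[1], z[2]))
}

oracle_perms <- local({
  p <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  p[apply(p, 1, function(r) length(unique(r)) == 4L), , drop = FALSE]
})

oracle_tau_star <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 4, length(y) == n)
  quads <- utils::combn(n, 4)
  tot <- 0
  for (q in seq_len(ncol(quads))) {
    idx <- quads[, q]
    for (p in seq_len(nrow(oracle_perms))) {
      ii <- idx[oracle_perms[p, ]]
      tot <- tot + oracle_kernel(x[ii]) * oracle_kernel(y[ii])
    }
  }
  tot / (n * (n - 1) * (n - 2) * (n - 3))
}

# random small instances with heavy ties in both margins
random_tied_instance <- function(n = sample(4:8, 1)) {
  x <- if (runif(1) < 0.5) sample(0:3, n, replace = TRUE) else runif(n)
  y <- if (runif(1) < 0.7) sample(0:2, n, replace = TRUE) else rnorm(n)
  list(x = x, y = y)
}
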