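# Per-gene testing pipeline: tau* + asymptotic (or permutation) p-value for
# every testable gene of a count matrix, with BH adjustment across genes.

#' Test configuration
#'
#' @param mode `"asymptotic"` (default; p-values from the limiting null law
#'   of the scaled statistic) or `"permutation"` (seeded permutation null
#'   per gene; slower, exact-rank validity).
#' @param B permutation replicates per gene (permutation mode; >= 100).
#' @param seed integer seed controlling all randomness of a run.
#' @param fdr_level target Benjamini-Hochberg FDR level in (0, 1).
#' @param min_nonzero_cells genes with fewer nonzero cells are not tested.
#' @param threads worker processes for the per-gene loop (results are
#'   independent of the thread count).
#' @return a `test_config` list.
#' @export
test_config <- function(mode = c("asymptotic", "permutation"), B = 1000L,
                        seed = 1L, fdr_level = 0.05,
                        min_nonzero_cells = 3L, threads = 1L) {
  mode <- match.arg(mode)
  if (fdr_level <= 0 || fdr_level >= 1) stop("fdr_level must be in (0, 1)")
  if (mode == "permutation" && B < 100) stop("B must be >= 100")
  structure(list(mode = mode, B = as.integer(B), seed = as.integer(seed),
                 fdr_level = fdr_level,
                 min_nonzero_cells = as.integer(min_nonzero_cells),
                 threads = as.integer(threads)),
            class = "test_config")
}

#' Flag genes as testable or not
#'
#' A gene cannot carry a tau* test when it is constant (a single unique
#' value makes the statistic identically zero) and is not worth testing when
#' expressed in fewer than `min_nonzero_cells` cells.
#'
#' @param counts cells-by-genes matrix (dense or `dgCMatrix`), or a
#'   `count_matrix_handle`.
#' @param min_nonzero_cells threshold on the number of nonzero cells.
#' @return data.frame with columns `gene_id`, `testable`, `reason`
#'   (`NA` when testable, else `"constant"` or `"too sparse"`).
#' @export
filter_genes <- function(counts, min_nonzero_cells = 3L) {
  counts <- as_count_matrix(counts)
  if (any(dim(counts) == 0)) stop("empty count matrix")
  nnz <- Matrix::colSums(counts != 0)
  constant <- vapply(seq_len(ncol(counts)),
                     function(g) length(unique(counts[, g])) == 1L,
                     logical(1))
  reason <- rep(NA_character_, ncol(counts))
  reason[nnz < min_nonzero_cells & !constant] <- "too sparse"
  reason[constant] <- "constant"
  data.frame(gene_id = colnames2(counts), testable = is.na(reason),
             reason = reason, stringsAsFactors = FALSE)
}

as_count_matrix <- function(counts) {
  if (inherits(counts, "count_matrix_handle")) counts$matrix else counts
}

colnames2 <- function(m) {
  if (!is.null(colnames(m))) colnames(m)
  else sprintf("gene%0*d", nchar(ncol(m)), seq_len(ncol(m)))
}

#' Test every gene for dependence on pseudotime
#'
#' Computes \eqn{\tau^*_n} with the fast tie-aware algorithm and a p-value
#' for every testable gene, then Benjamini-Hochberg q-values across tested
#' genes. Asymptotic null distributions are memoized across genes sharing a
#' (quantized) tie profile. Cells are aligned by identifier whenever both
#' the matrix and the pseudotime table carry them, otherwise positionally
#' (with a warning).
#'
#' @param counts cells-by-genes count matrix (dense, `dgCMatrix`, or a
#'   `count_matrix_handle` from the readers).
#' @param pseudotime a `pseudotime` object from [read_pseudotime_csv()], a
#'   data.frame with columns `cell_id` and `pseudotime`, or a bare numeric
#'   vector (positional alignment).
#' @param config a [test_config()].
#' @return data.frame of class `de_result_table`, one row per input gene:
#'   `gene_id`, `tau_star`, `scaled_stat`, `pvalue`, `qvalue`,
#'   `n_nonzero_cells`, `M_levels`, `algorithm_used`, `tested`, `reason`.
#' @export
test_all_genes <- function(counts, pseudotime, config = test_config()) {
  t0 <- proc.time()[["elapsed"]]
  counts <- as_count_matrix(counts)
  pt <- normalize_pseudotime(pseudotime)
  gene_ids <- colnames2(counts)
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")

  # cell alignment
  if (!is.null(pt$cell_id) && !is.null(rownames(counts))) {
    missing <- setdiff(pt$cell_id, rownames(counts))
    if (length(missing))
      stop("cells present in the pseudotime table but absent from the count ",
           "matrix: ", paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) ", ...")
    counts <- counts[match(pt$cell_id, rownames(counts)), , drop = FALSE]
  } else {
    if (nrow(counts) != length(pt$values))
      stop("count matrix has ", nrow(counts), " cells but pseudotime has ",
           length(pt$values))
    warning("aligning cells by position: no shared cell identifiers")
  }
  x <- pt$values
  n <- length(x)
  if (n < 4) stop("need at least 4 cells")

  x_tied <- anyDuplicated(x) > 0
  if (x_tied)
    log_info("pseudotime has tied values; per-gene statistics use the exact ",
             "O(n^2 log n) pairwise algorithm")
  x_tp <- if (x_tied) tie_profile(x) else NULL
  ord <- order(x)

  flags <- filter_genes(counts, config$min_nonzero_cells)
  log_info("testing ", sum(flags$testable), " of ", ncol(counts),
           " genes (n = ", n, " cells, mode = ", config$mode,
           ", seed = ", config$seed, ")")

  null_cache <- new.env(parent = emptyenv())
  nnz <- Matrix::colSums(counts != 0)

  test_one <- function(g) {
    if (!flags$testable[g])
      return(list(tau = NA_real_, p = NA_real_, M = NA_integer_,
                  algo = NA_character_))
    y <- as.numeric(counts[, g])
    tp <- tie_profile(y)
    if (!x_tied) {
      code <- match(y, tp$level_values)[ord]
      tau <- cpp_tau_fast_sorted(code, tp$M)
      algo <- "fast"
    } else {
      tau <- cpp_tau_pairwise(x, y)
      algo <- "pairwise"
    }
    if (config$mode == "asymptotic") {
      nul <- cached_null(null_cache, n, tp, x_tp)
      p <- nul$tail_fn(n * tau)
    } else {
      pn <- build_null_permutation(x, y, B = config$B,
                                   seed = config$seed + g)
      p <- (1 + sum(pn$draws >= tau)) / (config$B + 1)
    }
    list(tau = tau, p = p, M = tp$M, algo = algo)
  }

  res <- if (config$threads > 1L) {
    parallel::mclapply(seq_len(ncol(counts)), test_one,
                       mc.cores = config$threads, mc.preschedule = TRUE)
  } else {
    lapply(seq_len(ncol(counts)), test_one)
  }

  tau <- vapply(res, `[[`, numeric(1), "tau")
  p <- vapply(res, `[[`, numeric(1), "p")
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- adjust_fdr_bh(p[!is.na(p)])
  out <- data.frame(
    gene_id = gene_ids,
    tau_star = tau,
    scaled_stat = n * tau,
    pvalue = p,
    qvalue = q,
    n_nonzero_cells = as.integer(nnz),
    M_levels = vapply(res, `[[`, integer(1), "M"),
    algorithm_used = vapply(res, `[[`, character(1), "algo"),
    tested = flags$testable,
    reason = flags$reason,
    stringsAsFactors = FALSE
  )
  class(out) <- c("de_result_table", "data.frame")
  log_info("done in ", round(proc.time()[["elapsed"]] - t0, 2), " s")
  out
}

# accept the various pseudotime representations
normalize_pseudotime <- function(pt) {
  if (inherits(pt, "pseudotime"))
    return(list(values = pt$values, cell_id = pt$cell_ids))
  if (is.data.frame(pt)) {
    cols <- tolower(names(pt))
    ic <- match("cell_id", cols)
    iv <- match("pseudotime", cols)
    if (is.na(iv)) stop("pseudotime data.frame needs a 'pseudotime' column")
    v <- as.numeric(pt[[iv]])
    if (!all(is.finite(v))) stop("pseudotime values must be finite")
    return(list(values = v,
                cell_id = if (!is.na(ic)) as.character(pt[[ic]]) else NULL))
  }
  v <- as.numeric(pt)
  if (!all(is.finite(v))) stop("pseudotime values must be finite")
  list(values = v, cell_id = names(pt))
}

# memoized asymptotic nulls, keyed by (n, quantized tie profile); the law is
# built from the quantized profile so the key identifies it exactly
cached_null <- function(cache, n, tp, x_tp) {
  probs <- round(tp$level_probs, 4)
  probs <- probs / sum(probs)
  key <- paste0(n, ":", tp$M, ":", paste0(round(probs * 1e4), collapse = ","))
  got <- cache[[key]]
  if (!is.null(got)) return(got)
  nul <- build_null_asymptotic(n, probs, x_tie_profile = x_tp)
  assign(key, nul, envir = cache)
  nul
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH adjustment (via [stats::p.adjust()]); q-values are monotone in
#' the p-value ranking, at least the raw p-value, and at most 1.
#'
#' @param pvalues vector of p-values in \[0, 1\] (tested genes only).
#' @return vector of q-values, same order.
#' @export
adjust_fdr_bh <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

log_info <- function(...) {
  message("[pseudotau ", format(Sys.time(), "%H:%M:%S"), "] ", ...)
}
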