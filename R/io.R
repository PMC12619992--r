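# Readers and writers for the standard on-disk formats.
#
# Conventions: Matrix Market coordinate files are 1-based on disk and
# CellRanger-style triplets (matrix.mtx + features.tsv + barcodes.tsv) store
# genes x cells; matrices are transposed to the internal cells x genes
# orientation on read (recorded in `orientation_note`). CSV orientation is
# never guessed: the caller must state it.

maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

# declared nonzero count from the Matrix Market size line
mtx_declared_entries <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) return(NA_integer_)
    if (!startsWith(line, "%")) {
      dims <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
      return(if (length(dims) == 3 && !any(is.na(dims))) dims[3]
             else NA_integer_)
    }
  }
}

read_id_column <- function(path, what) {
  tab <- utils::read.delim(maybe_gz(path), header = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate identifiers in ", what, " file: ", path)
  ids
}

#' Read a CellRanger-style sparse count matrix
#'
#' Reads a Matrix Market coordinate file plus feature and barcode TSVs
#' (optionally gzipped). The on-disk matrix is genes x cells and is
#' transposed to cells x genes; integer counts are preserved exactly.
#'
#' @param matrix_path path to the `.mtx(.gz)` file.
#' @param features_path path to `features.tsv(.gz)` (gene ids in column 1).
#' @param barcodes_path path to `barcodes.tsv(.gz)` (cell barcodes).
#' @return object of class `count_matrix_handle`: list with `matrix`
#'   (`dgCMatrix`, cells x genes, dimnames set), `gene_ids`, `cell_ids`,
#'   `orientation_note`.
#' @export
read_counts_mtx <- function(matrix_path, features_path, barcodes_path) {
  m <- Matrix::readMM(maybe_gz(matrix_path))
  declared <- mtx_declared_entries(matrix_path)
  stored <- if (methods::is(m, "TsparseMatrix")) length(m@i) else length(m@x)
  if (!is.na(declared) && stored != declared)
    stop("matrix file ", matrix_path, " declares ", declared,
         " entries but contains ", stored, " (truncated file?)")
  genes <- read_id_column(features_path, "features")
  cells <- read_id_column(barcodes_path, "barcodes")
  if (nrow(m) != length(genes))
    stop("matrix file ", matrix_path, " has ", nrow(m), " rows but ",
         features_path, " lists ", length(genes), " features")
  if (ncol(m) != length(cells))
    stop("matrix file ", matrix_path, " has ", ncol(m), " columns but ",
         barcodes_path, " lists ", length(cells), " barcodes")
  m <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(m) <- list(cells, genes)
  structure(list(matrix = m, gene_ids = genes, cell_ids = cells,
                 orientation_note = "source was genes x cells; transposed"),
            class = "count_matrix_handle")
}

#' Read a dense CSV count matrix
#'
#' @param path CSV with a header row and the first column holding row
#'   identifiers.
#' @param orientation either `"cells_x_genes"` or `"genes_x_cells"`;
#'   required, never guessed from the shape.
#' @return a `count_matrix_handle` (see [read_counts_mtx()]).
#' @export
read_counts_csv <- function(path, orientation) {
  if (missing(orientation))
    stop("orientation must be given ('cells_x_genes' or 'genes_x_cells'); ",
         "it is never guessed")
  orientation <- match.arg(orientation, c("cells_x_genes", "genes_x_cells"))
  tab <- utils::read.csv(maybe_gz(path), header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (anyDuplicated(names(tab)[-1]))
    stop("duplicate column identifiers in ", path)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate row identifiers in ", path)
  tab <- tab[, -1, drop = FALSE]
  for (j in seq_along(tab)) {
    col <- tab[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      stop("non-numeric value in ", path, " at data row ",
           if (is.na(bad)) "?" else bad, ", column '", names(tab)[j], "'")
    }
  }
  m <- as.matrix(tab)
  rownames(m) <- ids
  if (orientation == "genes_x_cells") m <- t(m)
  if (anyDuplicated(rownames(m))) stop("duplicate cell identifiers in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate gene identifiers in ", path)
  sm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  structure(list(matrix = sm, gene_ids = colnames(sm), cell_ids = rownames(sm),
                 orientation_note = if (orientation == "genes_x_cells")
                   "source was genes x cells; transposed" else "as stored"),
            class = "count_matrix_handle")
}

#' @export
print.count_matrix_handle <- function(x, ...) {
  cat("Count matrix:", nrow(x$matrix), "cells x", ncol(x$matrix), "genes (",
      length(x$matrix@x), "stored entries;", x$orientation_note, ")\n")
  invisible(x)
}

#' Read a pseudotime table
#'
#' CSV with header and columns `cell_id` and `pseudotime` (case
#' insensitive). Rows with missing pseudotime (cells off the lineage) are
#' dropped with a warning reporting the count.
#'
#' @param path path to the CSV file.
#' @return object of class `pseudotime`: list with `values` (numeric) and
#'   `cell_ids`.
#' @export
read_pseudotime_csv <- function(path) {
  tab <- utils::read.csv(maybe_gz(path), header = TRUE,
                         stringsAsFactors = FALSE)
  cols <- tolower(names(tab))
  ic <- match("cell_id", cols)
  iv <- match("pseudotime", cols)
  if (is.na(ic) || is.na(iv))
    stop(path, " must have columns 'cell_id' and 'pseudotime' (found: ",
         paste(names(tab), collapse = ", "), ")")
  raw <- tab[[iv]]
  vals <- suppressWarnings(as.numeric(raw))
  bad <- !is.na(raw) & raw != "" & is.na(vals)
  if (any(bad))
    stop("non-numeric pseudotime in ", path, " at data row ", which(bad)[1])
  keep <- !is.na(vals)
  if (!any(keep)) stop("all pseudotime values in ", path, " are missing")
  if (any(!keep))
    warning(sum(!keep), " cell(s) without pseudotime dropped from ", path)
  ids <- as.character(tab[[ic]][keep])
  if (anyDuplicated(ids)) stop("duplicate cell identifiers in ", path)
  structure(list(values = vals[keep], cell_ids = ids), class = "pseudotime")
}

#' @export
print.pseudotime <- function(x, ...) {
  cat("Pseudotime for", length(x$values), "cells, range [",
      format(min(x$values), digits = 4), ",",
      format(max(x$values), digits = 4), "]\n")
  invisible(x)
}

#' Write a DE result table as TSV
#'
#' Fixed column order (gene, tau_star, scaled_stat, pvalue, qvalue,
#' n_nonzero_cells, M_levels, algorithm, tested, reason), floats at 6
#' significant digits, rows sorted by q-value then gene id (untested genes
#' last). Byte-identical output for identical tables.
#'
#' @param table a `de_result_table` from [test_all_genes()].
#' @param path output path.
#' @export
write_results_tsv <- function(table, path) {
  need <- c("gene_id", "tau_star", "scaled_stat", "pvalue", "qvalue",
            "n_nonzero_cells", "M_levels", "algorithm_used", "tested",
            "reason")
  if (!all(need %in% names(table)))
    stop("not a de_result_table: missing columns ",
         paste(setdiff(need, names(table)), collapse = ", "))
  tab <- table[order(table$qvalue, table$gene_id, method = "radix",
                     na.last = TRUE), need]
  for (cc in c("tau_star", "scaled_stat", "pvalue", "qvalue"))
    tab[[cc]] <- ifelse(is.na(tab[[cc]]), "", formatC(signif(tab[[cc]], 6),
                                                      format = "g", digits = 6))
  names(tab) <- c("gene", "tau_star", "scaled_stat", "pvalue", "qvalue",
                  "n_nonzero_cells", "M_levels", "algorithm", "tested",
                  "reason")
  tab$reason[is.na(tab$reason)] <- ""
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}
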