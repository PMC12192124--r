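#' Time-series single-cell expression container
#'
#' Bundles one cells-by-genes expression matrix per time point, with a
#' strictly increasing numeric time stamp (hours) for each, and a gene
#' ordering shared across all time points. Cells at different time points
#' are distinct (destructive sampling, as in scRNA-seq).
#'
#' @param matrices list of numeric matrices, one per time point, each
#'   cells x genes, non-negative, at least 2 cells and 2 genes. Column
#'   names, when present, must agree across time points.
#' @param times numeric vector of time stamps, strictly increasing, one
#'   per matrix.
#' @param genes optional character vector of gene identifiers; defaults to
#'   the column names of the first matrix, or `gene1..geneM`.
#'
#' @return An object of class `ts_expression`: a list with elements
#'   `matrices`, `times` and `genes`.
#' @examples
#' x <- ts_expression(
#'   list(matrix(rexp(20), 5, 4), matrix(rexp(20), 5, 4)),
#'   times = c(0, 1)
#' )
#' x
#' @export
ts_expression <- function(matrices, times, genes = NULL) {
  if (!is.list(matrices) || length(matrices) < 2L)
    stop("`matrices` must be a list of at least two matrices")
  if (length(times) != length(matrices))
    stop("`times` must have one entry per matrix")
  if (!is.numeric(times) || any(diff(times) <= 0))
    stop("`times` must be numeric and strictly increasing")
  m <- ncol(matrices[[1L]])
  if (is.null(genes)) {
    genes <- colnames(matrices[[1L]])
    if (is.null(genes)) genes <- paste0("gene", seq_len(m))
  }
  if (length(genes) != m || anyDuplicated(genes))
    stop("gene identifiers must be unique and match the matrix columns")
  matrices <- lapply(seq_along(matrices), function(i) {
    x <- as.matrix(matrices[[i]])
    storage.mode(x) <- "double"
    if (ncol(x) != m)
      stop("matrix ", i, " has ", ncol(x), " genes; expected ", m)
    if (nrow(x) < 2L || ncol(x) < 2L)
      stop("matrix ", i, " needs at least 2 cells and 2 genes")
    if (anyNA(x)) stop("matrix ", i, " contains NA/NaN values")
    if (any(x < 0)) stop("matrix ", i, " contains negative values")
    cn <- colnames(x)
    if (!is.null(cn) && !identical(cn, genes))
      stop("matrix ", i, " gene ordering differs from the shared ordering")
    colnames(x) <- genes
    x
  })
  structure(
    list(matrices = matrices, times = as.numeric(times), genes = genes),
    class = "ts_expression"
  )
}

#' @export
print.ts_expression <- function(x, ...) {
  cells <- vapply(x$matrices, nrow, integer(1))
  cat("Time-series single-cell expression\n")
  cat(sprintf("  %d genes, %d time points (t = %s h)\n",
              length(x$genes), length(x$times),
              paste(format(x$times, trim = TRUE), collapse = ", ")))
  cat(sprintf("  cells per time point: %s\n",
              paste(cells, collapse = ", ")))
  invisible(x)
}

#' Number of time points of a `ts_expression`
#' @param x a `ts_expression` object
#' @return integer number of time points
#' @export
n_timepoints <- function(x) {
  stopifnot(inherits(x, "ts_expression"))
  length(x$times)
}
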