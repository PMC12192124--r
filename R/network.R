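#' Subsampled temporal-variation replicates
#'
#' Repeats the temporal-variation computation on random subsamples of
#' cells: for each replicate, a fraction of cells is drawn without
#' replacement independently at every time point, and the
#' interval-normalized divergences are recomputed. The replicates are the
#' regression rows of the windowed VAR(1) fits. Replicate `r` is a pure
#' function of `seed + r`, so runs are bit-reproducible.
#'
#' @param data a [ts_expression()] object
#' @param measure a name from [divergence_measures()]
#' @param fraction fraction of cells drawn at each time point, in (0, 1]
#'   (default 0.8)
#' @param n_replicates number of subsampling replicates (default 100)
#' @param seed integer base seed
#' @param grid_size density-grid resolution passed to
#'   [temporal_variation()]
#' @return list of `n_replicates` `temporal_variation` objects
#' @export
subsample_variations <- function(data, measure = "js", fraction = 0.8,
                                 n_replicates = 100L, seed = 1L,
                                 grid_size = 512L) {
  stopifnot(inherits(data, "ts_expression"))
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  ncells <- vapply(data$matrices, nrow, integer(1))
  keep <- floor(fraction * ncells)
  if (any(keep < 2L))
    stop("subsample fraction leaves fewer than 2 cells at some time point")
  lapply(seq_len(n_replicates), function(r) {
    mats <- withr::with_seed(seed + r, lapply(seq_along(data$matrices),
      function(i) {
        idx <- sample.int(ncells[i], keep[i])
        data$matrices[[i]][idx, , drop = FALSE]
      }))
    sub <- ts_expression(mats, data$times, data$genes)
    temporal_variation(sub, measure, grid_size = grid_size)
  })
}

#' Assemble the regression problems of one sliding window
#'
#' Window `k` pairs the temporal-variation interval `k` (predictors) with
#' interval `k + 1` (responses): the design matrix stacks each
#' replicate's variation vector at interval `k` (N = number of
#' replicates), and for each target gene the response is the matching
#' replicate's variation at interval `k + 1`. The target gene's own
#' column is flagged for exclusion (no self-loops).
#'
#' @param variations list of `temporal_variation` objects (replicates)
#' @param window_index window number in `1..(T-2)`
#' @return list with `design` (N x m), `responses` (N x m, one column per
#'   target gene), `exclude` (per-gene excluded column = the gene
#'   itself), `genes` and `interval_pair`
#' @export
build_window_problems <- function(variations, window_index) {
  stopifnot(length(variations) >= 1L,
            inherits(variations[[1L]], "temporal_variation"))
  nint <- nrow(variations[[1L]]$values)
  if (window_index < 1L || window_index > nint - 1L)
    stop("`window_index` must be in 1..", nint - 1L)
  if (length(variations) == 1L)
    warning("a single replicate gives an under-determined regression")
  design <- t(vapply(variations, function(v) v$values[window_index, ],
                     numeric(ncol(variations[[1L]]$values))))
  responses <- t(vapply(variations, function(v) v$values[window_index + 1L, ],
                        numeric(ncol(variations[[1L]]$values))))
  genes <- colnames(variations[[1L]]$values)
  colnames(design) <- colnames(responses) <- genes
  list(design = design, responses = responses,
       exclude = seq_along(genes), genes = genes,
       interval_pair = variations[[1L]]$interval_starts[
         c(window_index, window_index + 1L)])
}

#' Spearman rank partial correlation matrix
#'
#' Rank-transforms every column, computes the Pearson correlation of the
#' ranks (= Spearman correlation), and converts the inverse correlation
#' matrix \eqn{\Omega} to partial correlations
#' \eqn{P_{ij} = -\Omega_{ij} / \sqrt{\Omega_{ii}\Omega_{jj}}}: the
#' association of each gene pair controlling for all other genes. A
#' ridge \eqn{\delta I} (\eqn{\delta = 10^{-3}}) is added when the rank
#' correlation matrix is singular or near-singular. Constant columns get
#' zero partial correlations with a warning.
#'
#' @param expr cells x genes numeric matrix
#' @param ridge ridge added to the correlation matrix if inversion fails
#'   (default 1e-3)
#' @return symmetric m x m matrix with unit diagonal
#' @export
spearman_partial_cor <- function(expr, ridge = 1e-3) {
  expr <- as.matrix(expr)
  m <- ncol(expr)
  if (m < 2L) stop("need at least 2 genes")
  const <- apply(expr, 2L, function(v) stats::sd(v) < .Machine$double.eps)
  if (any(const))
    warning("constant column(s): partial correlations set to 0 for ",
            paste(which(const), collapse = ", "))
  p <- diag(1, m)
  live <- which(!const)
  if (length(live) >= 2L) {
    ranks <- apply(expr[, live, drop = FALSE], 2L, rank)
    r <- stats::cor(ranks)
    omega <- tryCatch(solve(r), error = function(e) NULL)
    if (is.null(omega) || !all(is.finite(omega)) ||
        rcond(r) < 1e-10)
      omega <- solve(r + diag(ridge, length(live)))
    d <- sqrt(diag(omega))
    pc <- -omega / outer(d, d)
    diag(pc) <- 1
    pc <- (pc + t(pc)) / 2
    p[live, live] <- pc
  }
  dimnames(p) <- list(colnames(expr), colnames(expr))
  p
}

#' Sign matrix from partial correlations
#'
#' Elementwise sign: +1 activation, -1 inhibition, 0 no direct
#' relationship. Magnitudes below `tol` count as zero.
#'
#' @param p symmetric partial-correlation matrix
#' @param tol zero threshold (default 1e-12)
#' @return m x m matrix over \{-1, 0, +1\}
#' @export
sign_matrix <- function(p, tol = 1e-12) {
  s <- sign(p)
  s[abs(p) < tol] <- 0
  s
}

#' Fit time-varying signed gene regulatory networks
#'
#' The full inference pipeline. (1) Cells are subsampled (default 80%,
#' 100 replicates) and each replicate's interval-normalized divergence
#' matrix is computed ([subsample_variations()]). (2) A window slides
#' over consecutive interval pairs; within each window and for each
#' target gene, a penalized VAR(1) regression is fitted with the
#' regularization strength chosen by k-fold cross-validation over
#' replicate blocks; the gene's own column is removed from its design.
#' (3) The Spearman rank partial correlation of the pooled expression of
#' the three time points the window spans gives the sign matrix, and the
#' signed adjacency is the elementwise product of the coefficient matrix
#' and the signs. T input time points yield T - 2 window networks. The
#' whole procedure is deterministic given `seed`.
#'
#' @param data a [ts_expression()] object with at least 3 time points
#' @param measure divergence measure, see [divergence_measures()]
#'   (default `"js"`)
#' @param penalty `"lasso"`, `"scad"` or `"mcp"` (default `"mcp"`)
#' @param a concavity parameter of SCAD/MCP; defaults per
#'   [penalty_spec()]
#' @param fraction cell subsampling fraction (default 0.8)
#' @param n_replicates number of subsampling replicates (default 100)
#' @param n_folds cross-validation folds (default 10)
#' @param seed integer seed for subsampling and fold assignment
#' @param grid_size density-grid resolution
#' @param path_length,lambda_min_ratio lambda-path construction, see
#'   [cv_select_lambda()]
#' @param tol,max_iter coordinate-descent control
#' @param verbose print per-window progress
#' @return object of class `fdygrn`: list with `windows` (each holding
#'   `window_index`, `interval_pair`, `alpha`, `sign`, `adjacency` —
#'   `alpha[p, j]` is the influence of gene p on gene j), `genes`,
#'   `config` and `call`. Diagonals of `alpha` and `adjacency` are zero.
#' @examples
#' \donttest{
#' net <- random_grn(5, 0.3, seed = 1)
#' x <- simulate_sde(net, n_cells = 40, seed = 1)
#' fit <- fdygrn(x, n_replicates = 10, seed = 1)
#' fit
#' }
#' @export
fdygrn <- function(data, measure = "js",
                   penalty = c("mcp", "scad", "lasso"), a = NULL,
                   fraction = 0.8, n_replicates = 100L, n_folds = 10L,
                   seed = 1L, grid_size = 512L, path_length = 100L,
                   lambda_min_ratio = 0.001, tol = 1e-7,
                   max_iter = 10000L, verbose = FALSE) {
  stopifnot(inherits(data, "ts_expression"))
  penalty <- match.arg(penalty)
  measure <- match.arg(measure, divergence_measures())
  spec0 <- penalty_spec(penalty, lambda = NULL, a = a)
  tt <- data$times
  if (length(tt) < 3L) stop("at least 3 time points required")
  m <- length(data$genes)

  if (verbose) message("subsampling ", n_replicates, " replicates (",
                       measure, ")")
  variations <- subsample_variations(data, measure, fraction,
                                     n_replicates, seed, grid_size)

  # replicate-block fold assignment, shared across windows and genes
  nf <- n_folds
  if (n_replicates < nf) {
    warning(sprintf("only %d replicates; reducing folds from %d",
                    n_replicates, nf))
    nf <- n_replicates
  }
  fold <- withr::with_seed(seed + 10007L,
    sample(rep_len(seq_len(nf), n_replicates)))

  n_windows <- length(tt) - 2L
  windows <- vector("list", n_windows)
  for (k in seq_len(n_windows)) {
    if (verbose) message("window ", k, "/", n_windows)
    prob <- build_window_problems(variations, k)
    alpha <- fit_window_alpha(prob$design, prob$responses, spec0, fold,
                              path_length, lambda_min_ratio, tol, max_iter)
    pooled <- do.call(rbind, data$matrices[k:(k + 2L)])
    s <- sign_matrix(spearman_partial_cor(pooled))
    adjacency <- alpha * s
    diag(adjacency) <- 0
    dimnames(alpha) <- dimnames(adjacency) <- list(data$genes, data$genes)
    windows[[k]] <- list(window_index = k,
                         interval_pair = prob$interval_pair,
                         alpha = alpha, sign = s, adjacency = adjacency)
  }
  structure(list(
    windows = windows, genes = data$genes,
    config = list(measure = measure, penalty = penalty, a = spec0$a,
                  fraction = fraction, n_replicates = n_replicates,
                  n_folds = nf, seed = seed, grid_size = grid_size,
                  path_length = path_length,
                  lambda_min_ratio = lambda_min_ratio),
    call = match.call()
  ), class = "fdygrn")
}

# Cross-validated coefficient matrix of one window. Standardized designs
# and Gram matrices are shared across target genes (each gene only drops
# its own column), which keeps the per-gene cost at the coordinate-descent
# loop itself.
fit_window_alpha <- function(x, y, spec0, fold, path_length,
                             lambda_min_ratio, tol, max_iter) {
  n <- nrow(x)
  m <- ncol(x)
  nf <- max(fold)
  kind <- spec0$kind
  a <- spec0$a

  prep <- function(xtr, ytr) {
    std <- standardize_cols(xtr)
    yc <- sweep(ytr, 2L, colMeans(ytr), "-")
    list(std = std, gram = crossprod(std$xs) / nrow(xtr),
         xty = crossprod(std$xs, yc) / nrow(xtr),
         ybar = colMeans(ytr))
  }
  full <- prep(x, y)
  folds <- lapply(seq_len(nf), function(f) {
    tr <- fold != f
    c(prep(x[tr, , drop = FALSE], y[tr, , drop = FALSE]),
      list(xte = x[!tr, , drop = FALSE], yte = y[!tr, , drop = FALSE]))
  })

  alpha <- matrix(0, m, m)
  for (j in seq_len(m)) {
    act_full <- setdiff(which(!full$std$const), j)
    if (length(act_full) == 0L) next
    lmax <- max(abs(full$xty[act_full, j]), 0)
    if (lmax <= 0) next  # gene with no signal: all-zero column
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = path_length))
    sse <- numeric(path_length)
    for (fd in folds) {
      act <- setdiff(which(!fd$std$const), j)
      if (length(act) == 0L) {
        sse <- sse + sum((fd$yte[, j] - fd$ybar[j])^2)
        next
      }
      sol <- solve_path(fd$gram[act, act, drop = FALSE], fd$xty[act, j],
                        lambda, kind, a, tol = tol, max_iter = max_iter,
                        warn = FALSE)
      borig <- sol$beta / fd$std$scale[act]
      icpt <- fd$ybar[j] - drop(crossprod(borig, fd$std$center[act]))
      pred <- fd$xte[, act, drop = FALSE] %*% borig +
        matrix(icpt, nrow(fd$xte), path_length, byrow = TRUE)
      sse <- sse + colSums((fd$yte[, j] - pred)^2)
    }
    lam_opt <- lambda[which.min(sse)]
    sol <- solve_path(full$gram[act_full, act_full, drop = FALSE],
                      full$xty[act_full, j], lam_opt, kind, a,
                      tol = tol, max_iter = max_iter, warn = FALSE)
    alpha[act_full, j] <- sol$beta[, 1L] / full$std$scale[act_full]
  }
  alpha
}

#' @export
print.fdygrn <- function(x, ...) {
  cat("Time-varying signed regulatory network fit\n")
  cat(sprintf("  %d genes, %d windows; measure = %s, penalty = %s%s\n",
              length(x$genes), length(x$windows), x$config$measure,
              x$config$penalty,
              if (is.na(x$config$a)) "" else sprintf(" (a = %g)", x$config$a)))
  ec <- vapply(x$windows, function(w) sum(w$adjacency != 0), integer(1))
  cat(sprintf("  edges per window: %s\n", paste(ec, collapse = ", ")))
  invisible(x)
}

#' @export
summary.fdygrn <- function(object, ...) {
  ec <- vapply(object$windows, function(w) sum(w$adjacency != 0),
               integer(1))
  act <- vapply(object$windows, function(w) sum(w$adjacency > 0),
                integer(1))
  sim <- if (length(object$windows) > 1L)
    vapply(seq_len(length(object$windows) - 1L), function(i)
      consecutive_similarity(object$windows[[i]], object$windows[[i + 1L]]),
      numeric(1)) else numeric(0)
  out <- list(n_genes = length(object$genes),
              n_windows = length(object$windows),
              edges = ec, activating = act, inhibitory = ec - act,
              similarity = sim, config = object$config)
  class(out) <- "summary.fdygrn"
  out
}

#' @export
print.summary.fdygrn <- function(x, ...) {
  cat(sprintf("fdygrn fit: %d genes, %d windows (%s + %s)\n", x$n_genes,
              x$n_windows, x$config$measure, x$config$penalty))
  df <- data.frame(window = seq_len(x$n_windows), edges = x$edges,
                   activating = x$activating, inhibitory = x$inhibitory)
  print(df, row.names = FALSE)
  if (length(x$similarity))
    cat("consecutive-window similarity:",
        paste(round(x$similarity, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Extract signed adjacency matrices
#'
#' @param object an `fdygrn` fit
#' @param window window index, or `NULL` for a list of all windows
#' @param ... unused
#' @return a signed adjacency matrix (regulator rows, target columns), or
#'   a list of them
#' @export
coef.fdygrn <- function(object, window = NULL, ...) {
  if (is.null(window))
    return(lapply(object$windows, `[[`, "adjacency"))
  object$windows[[window]]$adjacency
}

#' Plot one window's signed network
#'
#' Draws the directed network of a single window: solid black arrows for
#' activation, dashed red arrows for inhibition.
#'
#' @param x an `fdygrn` fit
#' @param window which window to draw (default 1)
#' @param ... passed to [igraph::plot.igraph()]
#' @return the igraph object, invisibly
#' @export
plot.fdygrn <- function(x, window = 1L, ...) {
  adj <- x$windows[[window]]$adjacency
  idx <- which(adj != 0, arr.ind = TRUE)
  el <- data.frame(from = x$genes[idx[, 1L]], to = x$genes[idx[, 2L]],
                   weight = abs(adj[idx]), sign = sign(adj[idx]))
  g <- igraph::graph_from_data_frame(el, directed = TRUE,
                                     vertices = x$genes)
  cols <- ifelse(el$sign > 0, "black", "red")
  ltys <- ifelse(el$sign > 0, 1, 2)
  igraph::plot.igraph(g, edge.color = cols, edge.lty = ltys, ...)
  invisible(g)
}
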