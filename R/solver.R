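# Penalized least-squares by cyclic coordinate descent on standardized
# columns, covariance (Gram) updating. Conventions follow ncvreg: the
# objective is 1/(2N) ||y - Xb||^2 + sum_j p_lambda(b_j), columns are
# standardized to mean 0 and unit (population) variance internally, the
# intercept is unpenalized, and coefficients are returned on the original
# scale.

# standardize columns; returns scaled matrix plus centres/scales.
# Columns with (population) sd below `eps` are flagged constant and left
# as zeros so they drop out of the fit.
standardize_cols <- function(x, eps = 1e-12) {
  n <- nrow(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr, "-")
  scl <- sqrt(colMeans(xc^2))
  const <- scl < eps
  scl[const] <- 1
  xs <- sweep(xc, 2L, scl, "/")
  xs[, const] <- 0
  list(xs = xs, center = ctr, scale = scl, const = const)
}

# Coordinate-descent path solve on precomputed Gram quantities.
#   gram: t(Xs) %*% Xs / N over the active columns (unit diagonal)
#   xty:  t(Xs) %*% (y - mean(y)) / N
#   lambda: decreasing sequence; warm starts along the path
# Returns the standardized coefficient matrix (p x n_lambda) and the
# iteration counts. The inner loop is compiled (src/cd_solve.cpp).
solve_path <- function(gram, xty, lambda, kind, a, tol = 1e-7,
                       max_iter = 10000L, warn = TRUE) {
  kind_code <- match(kind, c("lasso", "scad", "mcp")) - 1L
  if (is.na(a)) a <- 0
  sol <- cd_solve_path(gram, as.numeric(xty), as.numeric(lambda),
                       kind_code, a, tol, as.integer(max_iter))
  if (warn && any(sol$iters >= max_iter))
    warning(sprintf("coordinate descent did not converge at lambda = %g",
                    lambda[which(sol$iters >= max_iter)[1L]]))
  sol
}

# Largest lambda with an all-zero solution (KKT bound for the lasso;
# shared by scad/mcp, whose thresholds coincide with soft-thresholding
# near zero).
lambda_max_from <- function(xty) max(abs(xty), 0)

#' Fit one penalized VAR(1) regression
#'
#' Solves \eqn{\min_\alpha \frac{1}{2N} \|y - X\alpha\|^2 +
#' \sum_p p_\lambda(\alpha_p)} by cyclic coordinate descent with
#' closed-form univariate updates ([univariate_threshold()]). Columns are
#' standardized internally; an unpenalized intercept is fitted; the
#' target gene's own column (`exclude`) is removed from the design so no
#' self-loop can be estimated. Coefficients are returned on the original
#' scale.
#'
#' @param x numeric design matrix, N x m (rows: replicate
#'   temporal-variation vectors at the predictor interval)
#' @param y numeric response vector of length N (the target gene's
#'   variation at the following interval)
#' @param spec a [penalty_spec()] with `lambda` set (the \eqn{\lambda} of
#'   the 1/N-scaled objective)
#' @param exclude optional column index clamped to zero throughout
#'   (self-regulation exclusion)
#' @param tol convergence tolerance on the maximum standardized
#'   coefficient change per sweep
#' @param max_iter sweep cap; non-convergence returns the best iterate
#'   with a warning
#' @return object of class `penvar_fit`: list with `alpha` (length-m
#'   coefficient vector, zeros at `exclude` and constant columns),
#'   `intercept`, `lambda`, `n_iter`, `converged`.
#' @export
fit_penalized_var <- function(x, y, spec, exclude = NULL, tol = 1e-7,
                              max_iter = 10000L) {
  stopifnot(inherits(spec, "penalty_spec"), !is.null(spec$lambda))
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (n < 2L) stop("need at least 2 rows")
  if (anyNA(x) || anyNA(y)) stop("NA/NaN in the regression problem")
  if (!is.null(exclude) && (exclude < 1L || exclude > m))
    stop("`exclude` out of range")
  std <- standardize_cols(x)
  active <- setdiff(which(!std$const), exclude)
  ybar <- mean(y)
  alpha <- numeric(m)
  n_iter <- 0L
  converged <- TRUE
  if (length(active) > 0L) {
    xs <- std$xs[, active, drop = FALSE]
    gram <- crossprod(xs) / n
    xty <- drop(crossprod(xs, y - ybar)) / n
    sol <- solve_path(gram, xty, spec$lambda, spec$kind, spec$a,
                      tol = tol, max_iter = max_iter)
    alpha[active] <- sol$beta[, 1L] / std$scale[active]
    n_iter <- sol$iters[1L]
    converged <- n_iter < max_iter
  }
  intercept <- ybar - sum(alpha * std$center)
  structure(list(alpha = alpha, intercept = intercept,
                 lambda = spec$lambda, n_iter = n_iter,
                 converged = converged, exclude = exclude),
            class = "penvar_fit")
}

#' @export
print.penvar_fit <- function(x, ...) {
  cat(sprintf("Penalized VAR fit: %d/%d nonzero, lambda = %g, %d sweeps\n",
              sum(x$alpha != 0), length(x$alpha), x$lambda, x$n_iter))
  invisible(x)
}

#' Select lambda by k-fold cross-validation
#'
#' Builds a log-spaced path of `path_length` lambda values from the
#' all-zero bound \eqn{\lambda_{max}} down to
#' `lambda_min_ratio` \eqn{\times \lambda_{max}}, solves the path on each
#' training fold with warm starts, and picks the lambda minimizing the
#' mean held-out squared error. Fold membership is assigned at the level
#' of `blocks` (e.g. subsampling replicates), so dependent rows from the
#' same replicate never straddle a train/test split.
#'
#' @inheritParams fit_penalized_var
#' @param spec a [penalty_spec()]; its `lambda` (if any) is ignored
#' @param n_folds number of folds (default 10); reduced to N with a
#'   warning when N < `n_folds`
#' @param path_length number of lambda values (default 100)
#' @param lambda_min_ratio floor of the path relative to
#'   \eqn{\lambda_{max}} (default 0.001)
#' @param seed integer seed governing the fold assignment
#' @param blocks optional integer/factor of length N grouping rows into
#'   replicate blocks; defaults to one block per row
#' @return list with `lambda_opt`, `lambda` (the path), `cvm` (mean CV
#'   squared error per path point), `fold` (fold id per row) and `fit`
#'   (the full-data [fit_penalized_var()] refit at `lambda_opt`)
#' @export
cv_select_lambda <- function(x, y, spec, exclude = NULL, n_folds = 10L,
                             path_length = 100L, lambda_min_ratio = 0.001,
                             seed = 1L, blocks = NULL, tol = 1e-7,
                             max_iter = 10000L) {
  stopifnot(inherits(spec, "penalty_spec"))
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(blocks)) blocks <- seq_len(n)
  blocks <- as.integer(factor(blocks))
  nb <- max(blocks)
  if (nb < n_folds) {
    warning(sprintf("only %d replicate blocks; reducing folds from %d",
                    nb, n_folds))
    n_folds <- nb
  }
  block_fold <- withr::with_seed(seed,
    sample(rep_len(seq_len(n_folds), nb)))
  fold <- block_fold[blocks]

  # path anchored at the full-data lambda_max
  std <- standardize_cols(x)
  active <- setdiff(which(!std$const), exclude)
  if (length(active) == 0L) stop("no usable predictor columns")
  xty_full <- drop(crossprod(std$xs[, active, drop = FALSE],
                             y - mean(y))) / n
  lmax <- lambda_max_from(xty_full)
  if (lmax <= 0) lmax <- 1e-6
  lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                    length.out = path_length))

  sse <- numeric(path_length)
  nheld <- 0L
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    te <- !tr
    if (!any(te) || sum(tr) < 2L) next
    pred <- predict_path(x[tr, , drop = FALSE], y[tr], x[te, , drop = FALSE],
                         lambda, spec, exclude, tol, max_iter)
    sse <- sse + colSums((y[te] - pred)^2)
    nheld <- nheld + sum(te)
  }
  cvm <- sse / nheld
  lambda_opt <- lambda[which.min(cvm)]
  fit <- fit_penalized_var(x, y, penalty_spec(spec$kind, lambda_opt, spec$a),
                           exclude = exclude, tol = tol, max_iter = max_iter)
  list(lambda_opt = lambda_opt, lambda = lambda, cvm = cvm, fold = fold,
       fit = fit)
}

# Fit the lambda path on (xtr, ytr) and return held-out predictions,
# one column per lambda.
predict_path <- function(xtr, ytr, xte, lambda, spec, exclude, tol,
                         max_iter) {
  n <- nrow(xtr)
  m <- ncol(xtr)
  std <- standardize_cols(xtr)
  active <- setdiff(which(!std$const), exclude)
  ybar <- mean(ytr)
  if (length(active) == 0L)
    return(matrix(ybar, nrow(xte), length(lambda)))
  xs <- std$xs[, active, drop = FALSE]
  gram <- crossprod(xs) / n
  xty <- drop(crossprod(xs, ytr - ybar)) / n
  sol <- solve_path(gram, xty, lambda, spec$kind, spec$a, tol = tol,
                    max_iter = max_iter, warn = FALSE)
  beta_orig <- sol$beta / std$scale[active]          # p x nl
  icpt <- ybar - drop(crossprod(beta_orig, std$center[active]))
  xte[, active, drop = FALSE] %*% beta_orig +
    matrix(icpt, nrow(xte), length(lambda), byrow = TRUE)
}
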