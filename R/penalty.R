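#' Sparsity penalty specification
#'
#' Describes one of the three penalties used for sparse VAR(1) fitting:
#' LASSO \eqn{\lambda |\alpha|}, SCAD (smoothly clipped absolute
#' deviation) or MCP (minimax concave penalty). SCAD and MCP taper off
#' for large coefficients, which debiases strong edges and yields
#' smoother network evolution across windows than the LASSO.
#'
#' @param kind `"lasso"`, `"scad"` or `"mcp"`
#' @param lambda regularization strength, non-negative; may be `NULL`
#'   when the spec only names a penalty family (e.g. for
#'   cross-validation).
#' @param a concavity parameter: must exceed 2 for SCAD (default 3.7)
#'   and 1 for MCP (default 3); ignored for the LASSO.
#' @return object of class `penalty_spec`
#' @examples
#' penalty_spec("mcp", lambda = 0.1)
#' @export
penalty_spec <- function(kind = c("lasso", "scad", "mcp"), lambda = NULL,
                         a = NULL) {
  kind <- match.arg(kind)
  if (!is.null(lambda)) {
    if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 ||
        !is.finite(lambda))
      stop("`lambda` must be a single non-negative number")
  }
  if (kind == "lasso") {
    a <- NA_real_
  } else {
    if (is.null(a)) a <- if (kind == "scad") 3.7 else 3
    if (kind == "scad" && a <= 2) stop("SCAD requires a > 2")
    if (kind == "mcp" && a <= 1) stop("MCP requires a > 1")
  }
  structure(list(kind = kind, lambda = lambda, a = a),
            class = "penalty_spec")
}

#' @export
print.penalty_spec <- function(x, ...) {
  cat(sprintf("Penalty: %s, lambda = %s%s\n", x$kind,
              if (is.null(x$lambda)) "(path)" else format(x$lambda),
              if (is.na(x$a)) "" else sprintf(", a = %g", x$a)))
  invisible(x)
}

#' Penalty function value
#'
#' Exact piecewise evaluation of the penalty at the given coefficient
#' values. LASSO: \eqn{\lambda|\alpha|}. SCAD:
#' \eqn{\lambda|\alpha|} for \eqn{|\alpha| \le \lambda},
#' \eqn{(2a\lambda|\alpha| - \alpha^2 - \lambda^2) / (2(a-1))} for
#' \eqn{\lambda < |\alpha| \le a\lambda}, and the constant
#' \eqn{(a+1)\lambda^2/2} beyond. MCP:
#' \eqn{\lambda|\alpha| - \alpha^2/(2a)} for \eqn{|\alpha| \le a\lambda},
#' constant \eqn{a\lambda^2/2} beyond. All are continuous and
#' non-decreasing in \eqn{|\alpha|}.
#'
#' @param spec a [penalty_spec()] with `lambda` set
#' @param coef numeric vector of coefficient values
#' @return non-negative numeric vector, same length as `coef`
#' @export
penalty_value <- function(spec, coef) {
  stopifnot(inherits(spec, "penalty_spec"), !is.null(spec$lambda))
  lam <- spec$lambda
  a <- spec$a
  t <- abs(coef)
  switch(spec$kind,
    lasso = lam * t,
    scad = ifelse(t <= lam, lam * t,
           ifelse(t <= a * lam,
                  (2 * a * lam * t - t^2 - lam^2) / (2 * (a - 1)),
                  (a + 1) * lam^2 / 2)),
    mcp = ifelse(t <= a * lam, lam * t - t^2 / (2 * a), a * lam^2 / 2)
  )
}

#' Penalty derivative (shrinkage profile)
#'
#' First derivative of the penalty with respect to the coefficient
#' magnitude. SCAD: \eqn{\lambda} for \eqn{|\alpha| \le \lambda}, then
#' \eqn{(a\lambda - |\alpha|)_+ / (a-1)}; MCP:
#' \eqn{\lambda (1 - |\alpha|/(a\lambda))_+}. Both vanish for large
#' coefficients, which is the debiasing property.
#'
#' @param spec a [penalty_spec()] with `lambda` set
#' @param coef non-negative coefficient magnitudes
#' @return non-negative numeric vector
#' @export
penalty_derivative <- function(spec, coef) {
  stopifnot(inherits(spec, "penalty_spec"), !is.null(spec$lambda))
  if (any(coef < 0)) stop("`coef` must be non-negative (magnitudes)")
  lam <- spec$lambda
  a <- spec$a
  switch(spec$kind,
    lasso = rep(lam, length(coef)),
    scad = ifelse(coef <= lam, lam, pmax(a * lam - coef, 0) / (a - 1)),
    mcp = lam * pmax(1 - coef / (a * lam), 0)
  )
}

# Scalar thresholding used inside the coordinate-descent loops; closed-form
# solution of  argmin_b 1/2 (z - b)^2 + p_lambda(b)  for a standardized
# (unit-variance) column.
threshold1 <- function(z, lam, kind, a) {
  az <- abs(z)
  if (kind == "lasso") {
    if (az <= lam) return(0)
    return(sign(z) * (az - lam))
  }
  if (kind == "scad") {
    if (az <= 2 * lam) {
      if (az <= lam) return(0)
      return(sign(z) * (az - lam))
    }
    if (az <= a * lam) {
      s <- az - a * lam / (a - 1)
      if (s < 0) s <- 0
      return(sign(z) * s * (a - 1) / (a - 2))
    }
    return(z)
  }
  # mcp
  if (az <= a * lam) {
    if (az <= lam) return(0)
    return(sign(z) * (az - lam) * a / (a - 1))
  }
  z
}

#' Univariate penalized least-squares solution
#'
#' Closed-form minimizer of \eqn{\frac12 (z - \beta)^2 + p_\lambda(\beta)}
#' for a standardized column: the soft-threshold for the LASSO, the
#' firm-threshold forms for SCAD and MCP. This is the inner solve of the
#' coordinate-descent algorithm.
#'
#' @param spec a [penalty_spec()] with `lambda` set
#' @param z numeric vector of unpenalized univariate solutions
#' @return numeric vector of minimizers, same length as `z`
#' @examples
#' univariate_threshold(penalty_spec("lasso", 1), 3)  # 2
#' @export
univariate_threshold <- function(spec, z) {
  stopifnot(inherits(spec, "penalty_spec"), !is.null(spec$lambda))
  vapply(z, threshold1, numeric(1), lam = spec$lambda, kind = spec$kind,
         a = spec$a)
}
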