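#' Random signed gold-standard regulatory network
#'
#' Draws a directed network over `n_genes` genes: every ordered non-self
#' pair carries an edge independently with probability `edge_density`,
#' signed +1 (activation) with probability `activation_prob` and -1
#' (inhibition) otherwise. Self-regulation is excluded by construction.
#' An empty draw is resampled so at least one edge always exists.
#'
#' @param n_genes number of genes (>= 2)
#' @param edge_density edge probability per ordered pair, in (0, 1]
#' @param activation_prob probability that an edge is activating
#' @param seed optional integer seed
#' @return object of class `grn`: list with `genes` and `edges`
#'   (data.frame `regulator`, `target`, `sign`)
#' @examples
#' random_grn(10, 0.15, seed = 1)
#' @export
random_grn <- function(n_genes, edge_density = 0.15,
                       activation_prob = 0.5, seed = NULL) {
  if (n_genes < 2L) stop("need at least 2 genes")
  if (edge_density <= 0 || edge_density > 1)
    stop("`edge_density` must be in (0, 1]")
  genes <- paste0("gene", seq_len(n_genes))
  pairs <- expand.grid(regulator = seq_len(n_genes),
                       target = seq_len(n_genes))
  pairs <- pairs[pairs$regulator != pairs$target, ]
  draw <- function() {
    present <- stats::runif(nrow(pairs)) < edge_density
    sgn <- ifelse(stats::runif(nrow(pairs)) < activation_prob, 1, -1)
    data.frame(regulator = genes[pairs$regulator[present]],
               target = genes[pairs$target[present]],
               sign = sgn[present], stringsAsFactors = FALSE)
  }
  body <- function() {
    edges <- draw()
    while (nrow(edges) == 0L) edges <- draw()
    edges
  }
  edges <- if (is.null(seed)) body() else withr::with_seed(seed, body())
  rownames(edges) <- NULL
  structure(list(genes = genes, edges = edges), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("Signed regulatory network: %d genes, %d edges (%d+/%d-)\n",
              length(x$genes), nrow(x$edges), sum(x$edges$sign > 0),
              sum(x$edges$sign < 0)))
  invisible(x)
}

#' Simulate single-cell expression snapshots from a signed network
#'
#' Integrates, per cell, the stochastic kinetics
#' \deqn{dx_i = (V \cdot reg_i(x) - \gamma x_i)\,dt + \sigma\,dW_i}
#' by Euler-Maruyama, where \eqn{reg_i} is the product of Hill terms over
#' gene i's regulators — \eqn{x_r^h / (K^h + x_r^h)} for an activator,
#' \eqn{K^h / (K^h + x_r^h)} for a repressor — and 0.5 for unregulated
#' genes. State is clipped at zero after every step. Cells recorded at
#' different time points are distinct trajectories (destructive sampling,
#' as in scRNA-seq); each trajectory starts from an independent
#' uniform(0, V/gamma) state at t = 0.
#'
#' @param grn a [random_grn()]-style `grn` object
#' @param n_cells cells recorded per time point (default 100)
#' @param times increasing sampling times in hours (default the
#'   0-96 h eight-point grid of PMA-stimulated THP-1 differentiation,
#'   an unevenly spaced template)
#' @param V maximal production rate (default 2)
#' @param gamma first-order decay rate per hour (default 0.2)
#' @param K Hill half-saturation constant (default 1)
#' @param hill Hill coefficient (default 2)
#' @param sigma additive noise intensity (default 0.1)
#' @param dt Euler-Maruyama step in hours (default 0.05); must be
#'   smaller than a tenth of the smallest sampling interval
#' @param seed optional integer seed
#' @return a [ts_expression()] object
#' @export
simulate_sde <- function(grn, n_cells = 100L,
                         times = c(0, 1, 6, 12, 24, 48, 72, 96),
                         V = 2, gamma = 0.2, K = 1, hill = 2,
                         sigma = 0.1, dt = 0.05, seed = NULL) {
  stopifnot(inherits(grn, "grn"))
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(c(V, gamma, K, hill) <= 0)) stop("all rates must be positive")
  pos_gaps <- diff(sort(unique(c(0, times))))
  if (dt >= min(pos_gaps)) stop("`dt` must be below the smallest interval")
  if (dt > min(pos_gaps) / 10)
    stop("`dt` must be below a tenth of the smallest sampling interval")
  m <- length(grn$genes)
  ridx <- match(grn$edges$regulator, grn$genes)
  tidx <- match(grn$edges$target, grn$genes)
  esign <- grn$edges$sign
  kh <- K^hill

  regulated <- unique(tidx)
  step_to <- function(x, t_end) {
    nstep <- round(t_end / dt)
    sq <- sigma * sqrt(dt)
    for (s in seq_len(nstep)) {
      reg <- matrix(0.5, nrow(x), m)
      reg[, regulated] <- 1
      for (e in seq_along(ridx)) {
        hx <- x[, ridx[e]]^hill
        f <- if (esign[e] > 0) hx / (kh + hx) else kh / (kh + hx)
        reg[, tidx[e]] <- reg[, tidx[e]] * f
      }
      x <- x + (V * reg - gamma * x) * dt +
        if (sigma > 0) sq * matrix(stats::rnorm(length(x)), nrow(x), m)
        else 0
      x[x < 0] <- 0
    }
    x
  }
  body <- function() {
    lapply(times, function(tp) {
      x0 <- matrix(stats::runif(n_cells * m, 0, V / gamma), n_cells, m)
      x <- step_to(x0, tp)
      colnames(x) <- grn$genes
      x
    })
  }
  mats <- if (is.null(seed)) body() else withr::with_seed(seed, body())
  ts_expression(mats, times, grn$genes)
}

#' Apply dropout to an expression time series
#'
#' Sets each matrix entry to zero independently with probability `rate`,
#' mimicking scRNA-seq technical dropout. Deterministic under `seed`.
#'
#' @param data a [ts_expression()] object
#' @param rate dropout probability in `[0, 1)`
#' @param seed optional integer seed
#' @return a [ts_expression()] object
#' @export
add_dropout <- function(data, rate, seed = NULL) {
  stopifnot(inherits(data, "ts_expression"))
  if (rate < 0 || rate >= 1) stop("`rate` must be in [0, 1)")
  if (rate == 0) return(data)
  body <- function() {
    lapply(data$matrices, function(x) {
      x[matrix(stats::runif(length(x)) < rate, nrow(x), ncol(x))] <- 0
      x
    })
  }
  mats <- if (is.null(seed)) body() else withr::with_seed(seed, body())
  ts_expression(mats, data$times, data$genes)
}
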