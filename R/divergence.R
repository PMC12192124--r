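#' Supported divergence measures
#'
#' The eight f-divergences plus the Kolmogorov-Smirnov distance available
#' for quantifying per-gene distributional change between consecutive
#' time points. All KL-family quantities use natural logarithms (nats).
#' The `neyman` entry is the variant
#' \eqn{\int p (p/q - 1)^2 dx} (weighting by \eqn{p}), which differs from
#' the conventional Neyman chi-squared \eqn{\int (p-q)^2/p \, dx}.
#'
#' @return character vector of measure names
#' @export
divergence_measures <- function() {
  c("forward_kl", "reverse_kl", "symmetric_kl", "js",
    "pearson", "neyman", "symmetric_pearson", "js_pearson", "ks")
}

silverman_bw <- function(x) {
  if (stats::sd(x) < .Machine$double.eps) {
    warning("zero-variance sample; falling back to bandwidth max(0.1*|mean|, 1e-3)")
    return(max(0.1 * abs(mean(x)), 1e-3))
  }
  stats::bw.nrd0(x)
}

#' Gaussian kernel density estimate on an explicit grid
#'
#' Estimates the probability density of a sample of expression values by
#' a Gaussian kernel density estimate evaluated on a shared grid, floored
#' at a small positive constant and renormalized so the trapezoidal
#' integral over the grid is exactly one. The floor keeps ratio-based
#' divergence integrands finite where the two samples' supports do not
#' overlap (routine under scRNA-seq dropout).
#'
#' @param sample numeric vector of observed values, length >= 2.
#' @param grid optional strictly increasing numeric grid on which to
#'   evaluate the density; when `NULL` a grid of `grid_size` points
#'   spanning `range(sample)` padded by `pad` bandwidths is used.
#' @param grid_size number of grid points when `grid` is `NULL`
#'   (default 512, minimum 64).
#' @param bandwidth kernel bandwidth; default Silverman's rule-of-thumb
#'   (`bw.nrd0`). A zero-variance sample falls back to
#'   `max(0.1 * |mean|, 1e-3)` with a warning.
#' @param pad grid padding in bandwidths (default 3).
#' @param floor_eps density floor before renormalization (default 1e-12).
#'
#' @return object of class `density_estimate`: list with `grid`,
#'   `density` and `bandwidth`.
#' @examples
#' d <- estimate_density(rnorm(1000))
#' pracma::trapz(d$grid, d$density)  # 1
#' @export
estimate_density <- function(sample, grid = NULL, grid_size = 512L,
                             bandwidth = NULL, pad = 3, floor_eps = 1e-12) {
  if (length(sample) == 0L) stop("empty sample")
  if (length(sample) < 2L) stop("sample must contain at least 2 values")
  if (anyNA(sample)) stop("sample contains NA/NaN")
  if (is.null(bandwidth)) bandwidth <- silverman_bw(sample)
  if (is.null(grid)) {
    if (grid_size < 64L) stop("grid_size must be at least 64")
    lo <- min(sample) - pad * bandwidth
    hi <- max(sample) + pad * bandwidth
    grid <- seq(lo, hi, length.out = grid_size)
  } else {
    if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  }
  # mean of Gaussian kernels centred at the sample points; equispaced
  # grids go through the binned-FFT evaluation of stats::density()
  dg <- diff(grid)
  if (max(dg) - min(dg) < 1e-8 * mean(dg)) {
    dens <- stats::density(sample, bw = bandwidth, kernel = "gaussian",
                           from = grid[1L], to = grid[length(grid)],
                           n = length(grid))$y
  } else {
    dens <- colMeans(stats::dnorm(outer(sample, grid, "-"), sd = bandwidth))
  }
  dens <- pmax(dens, floor_eps)
  dens <- dens / pracma::trapz(grid, dens)
  structure(list(grid = grid, density = dens, bandwidth = bandwidth),
            class = "density_estimate")
}

#' f-divergence between two density estimates
#'
#' Evaluates \eqn{D_f(P \| Q) = \int q(x) f(p(x)/q(x)) dx} by trapezoidal
#' quadrature on the shared grid of the two density estimates. Available
#' measures (natural log throughout):
#' * `forward_kl`: \eqn{\int p \log(p/q)}
#' * `reverse_kl`: \eqn{\int q \log(q/p)}
#' * `symmetric_kl`: average of forward and reverse KL
#' * `js`: Jensen-Shannon, KL of each argument against the mixture
#'   \eqn{M = (P+Q)/2}; bounded by \eqn{\log 2}
#' * `pearson`: \eqn{\int q (p/q - 1)^2}
#' * `neyman`: \eqn{\int p (p/q - 1)^2} (see [divergence_measures()])
#' * `symmetric_pearson`: average of Pearson in both directions
#' * `js_pearson`: average of Pearson of each argument against \eqn{M}
#'
#' Tiny negative quadrature artifacts are clipped to zero.
#'
#' @param p,q `density_estimate` objects on the identical grid.
#' @param measure one of the names above (`ks` is not valid here; use
#'   [ks_distance()] on raw samples).
#' @return non-negative scalar divergence
#' @examples
#' g <- seq(-5, 8, length.out = 512)
#' p <- estimate_density(rnorm(2000, 1), grid = g)
#' q <- estimate_density(rnorm(2000, 0), grid = g)
#' f_divergence(p, q, "forward_kl")  # about 0.5
#' @export
f_divergence <- function(p, q, measure) {
  stopifnot(inherits(p, "density_estimate"), inherits(q, "density_estimate"))
  measure <- match.arg(measure, setdiff(divergence_measures(), "ks"))
  if (length(p$grid) != length(q$grid) || !all(p$grid == q$grid))
    stop("p and q must be estimated on the identical grid")
  g <- p$grid
  pd <- p$density
  qd <- q$density
  tz <- function(y) pracma::trapz(g, y)
  kl <- function(a, b) tz(a * log(a / b))
  val <- switch(measure,
    forward_kl = kl(pd, qd),
    reverse_kl = kl(qd, pd),
    symmetric_kl = 0.5 * (kl(pd, qd) + kl(qd, pd)),
    js = {
      m <- (pd + qd) / 2
      0.5 * kl(pd, m) + 0.5 * kl(qd, m)
    },
    pearson = tz(qd * (pd / qd - 1)^2),
    neyman = tz(pd * (pd / qd - 1)^2),
    symmetric_pearson = 0.5 * (tz(qd * (pd / qd - 1)^2) +
                               tz(pd * (qd / pd - 1)^2)),
    js_pearson = {
      m <- (pd + qd) / 2
      0.5 * tz(m * (pd / m - 1)^2) + 0.5 * tz(m * (qd / m - 1)^2)
    }
  )
  max(val, 0)
}

#' Kolmogorov-Smirnov distance between two samples
#'
#' Maximum absolute difference between the two empirical cumulative
#' distribution functions, evaluated over the pooled sample points. This
#' is the baseline temporal-variation measure used by regression-on-ECDF
#' methods such as SINCERITIES.
#'
#' @param sample_p,sample_q non-empty numeric vectors
#' @return scalar in `[0, 1]`
#' @examples
#' ks_distance(c(1, 2), c(1, 2, 3))  # 1/3
#' @export
ks_distance <- function(sample_p, sample_q) {
  if (length(sample_p) == 0L || length(sample_q) == 0L)
    stop("samples must be non-empty")
  if (anyNA(sample_p) || anyNA(sample_q)) stop("samples contain NA/NaN")
  pts <- sort(unique(c(sample_p, sample_q)))
  fp <- stats::ecdf(sample_p)
  fq <- stats::ecdf(sample_q)
  max(abs(fp(pts) - fq(pts)))
}

#' Interval-normalized temporal variation of every gene
#'
#' For each gene and each pair of consecutive time points, estimates the
#' divergence between the gene's expression distributions at the two time
#' points and divides by the interval length \eqn{\Delta t_l} in hours,
#' making values comparable across unevenly spaced intervals. For
#' f-divergences both densities are estimated on one shared grid spanning
#' the pooled sample range padded by three bandwidths; `ks` operates on
#' the raw samples.
#'
#' @param data a [ts_expression()] object with at least 2 time points
#' @param measure a name from [divergence_measures()]
#' @param grid_size shared-grid resolution for the density estimates
#' @return object of class `temporal_variation`: list with `values`
#'   ((T-1) x genes matrix of non-negative reals, rows ordered by
#'   interval), `interval_starts`, `dt` and `measure`.
#' @export
temporal_variation <- function(data, measure = "js", grid_size = 512L) {
  stopifnot(inherits(data, "ts_expression"))
  measure <- match.arg(measure, divergence_measures())
  tt <- data$times
  if (length(tt) < 2L) stop("at least 2 time points required")
  if (any(diff(tt) <= 0)) stop("time stamps must be strictly increasing")
  nint <- length(tt) - 1L
  m <- length(data$genes)
  vals <- matrix(0, nint, m, dimnames = list(NULL, data$genes))
  for (l in seq_len(nint)) {
    dt <- tt[l + 1L] - tt[l]
    xa <- data$matrices[[l]]
    xb <- data$matrices[[l + 1L]]
    for (j in seq_len(m)) {
      a <- xa[, j]
      b <- xb[, j]
      if (measure == "ks") {
        d <- ks_distance(a, b)
      } else {
        bwa <- silverman_bw(a)
        bwb <- silverman_bw(b)
        pad <- 3 * max(bwa, bwb)
        grid <- seq(min(a, b) - pad, max(a, b) + pad,
                    length.out = grid_size)
        pa <- estimate_density(a, grid = grid, bandwidth = bwa)
        pb <- estimate_density(b, grid = grid, bandwidth = bwb)
        # divergence of the later distribution from the earlier one
        d <- f_divergence(pb, pa, measure)
      }
      vals[l, j] <- d / dt
    }
  }
  structure(list(values = vals, interval_starts = tt[seq_len(nint)],
                 dt = diff(tt), measure = measure),
            class = "temporal_variation")
}

#' @export
print.temporal_variation <- function(x, ...) {
  cat(sprintf("Temporal variation (%s): %d intervals x %d genes\n",
              x$measure, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write a temporal-variation matrix as TSV
#'
#' One row per interval; first column is the interval start time, the
#' remaining columns are the genes.
#'
#' @param tv a `temporal_variation` object
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_temporal_variation <- function(tv, path) {
  stopifnot(inherits(tv, "temporal_variation"))
  df <- data.frame(interval_start = tv$interval_starts,
                   tv$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
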