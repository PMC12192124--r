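# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct formula transcriptions, grid searches
# and exhaustive enumerations.

# Direct transcription of the piecewise penalty definitions.
oracle_penalty <- function(kind, lam, a, alpha) {
  t <- abs(alpha)
  if (kind == "lasso") return(lam * t)
  if (kind == "scad") {
    if (t <= lam) return(lam * t)
    if (t <= a * lam) return((2 * a * lam * t - t^2 - lam^2) / (2 * (a - 1)))
    return((a + 1) * lam^2 / 2)
  }
  if (t <= a * lam) return(lam * t - t^2 / (2 * a))
  a * lam^2 / 2
}

oracle_penalty_deriv <- function(kind, lam, a, t) {
  if (kind == "lasso") return(lam)
  if (kind == "scad") {
    if (t <= lam) return(lam)
    return(max(a * lam - t, 0) / (a - 1))
  }
  lam * max(1 - t / (a * lam), 0)
}

# Coarse-to-fine grid search for argmin_b 1/2 (z-b)^2 + p(b); the 1-D
# inner problem of coordinate descent.
oracle_threshold <- function(kind, lam, a, z, lo = -8, hi = 8) {
  obj <- function(b) 0.5 * (z - b)^2 +
    vapply(b, function(bb) oracle_penalty(kind, lam, a, bb), numeric(1))
  g <- seq(lo, hi, length.out = 16001L)
  b0 <- g[which.min(obj(g))]
  step <- g[2] - g[1]
  g2 <- seq(b0 - step, b0 + step, length.out = 4001L)
  g2[which.min(obj(g2))]
}

# Partial correlation of ranked data by regressing out all other columns
# (the textbook residual definition).
oracle_partial_cor <- function(x, i, j) {
  r <- apply(x, 2, rank)
  others <- r[, -c(i, j), drop = FALSE]
  ri <- stats::resid(stats::lm(r[, i] ~ others))
  rj <- stats::resid(stats::lm(r[, j] ~ others))
  stats::cor(ri, rj)
}

# Exhaustive Mann-Whitney enumeration of the sign-aware AUROC: positives
# are the gold edges (scored by a correctly signed prediction, else 0);
# negatives are non-gold pairs plus wrong-signed predictions on gold
# pairs. Counts every (positive, negative) pair, ties worth one half.
oracle_signed_auroc <- function(predictions, gold) {
  genes <- gold$genes
  pairs <- expand.grid(regulator = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  get_pred <- function(r, t) {
    hit <- predictions$regulator == r & predictions$target == t
    if (any(hit)) c(predictions$score[hit][1], predictions$sign[hit][1])
    else c(0, 0)
  }
  pos <- numeric(0)
  neg <- numeric(0)
  for (k in seq_len(nrow(pairs))) {
    r <- pairs$regulator[k]; t <- pairs$target[k]
    p <- get_pred(r, t)
    hit <- gold$edges$regulator == r & gold$edges$target == t
    if (any(hit)) {
      gs <- gold$edges$sign[hit][1]
      pos <- c(pos, if (p[2] == gs) p[1] else 0)
      if (p[2] != 0 && p[2] != gs) neg <- c(neg, p[1])
    } else {
      neg <- c(neg, p[1])
    }
  }
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Small deterministic benchmark used by several suites.
make_benchmark <- function(n_genes = 5, n_cells = 40, seed = 11,
                           sigma = 0.1, edge_density = 0.3) {
  net <- random_grn(n_genes, edge_density, seed = seed)
  data <- simulate_sde(net, n_cells = n_cells, sigma = sigma, seed = seed)
  list(net = net, data = data)
}

# A window-network stub from an explicit signed edge list.
window_from_edges <- function(genes, edges) {
  adj <- matrix(0, length(genes), length(genes),
                dimnames = list(genes, genes))
  for (k in seq_len(nrow(edges)))
    adj[edges$regulator[k], edges$target[k]] <-
      edges$sign[k] * edges$weight[k]
  list(window_index = 1L, interval_pair = c(0, 1), alpha = abs(adj),
       sign = sign(adj), adjacency = adj)
}
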