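test_that("subsampling replicates are reproducible and respect the fraction", {
  bm <- make_benchmark(n_genes = 3, n_cells = 20, seed = 31)
  v1 <- subsample_variations(bm$data, "ks", 0.8, 5, seed = 9)
  v2 <- subsample_variations(bm$data, "ks", 0.8, 5, seed = 9)
  expect_identical(v1, v2)
  expect_length(v1, 5)
  # fraction 1 samples every cell: replicates coincide
  vf <- subsample_variations(bm$data, "ks", 1.0, 3, seed = 9)
  expect_equal(vf[[1]]$values, vf[[2]]$values)
  expect_equal(vf[[2]]$values, vf[[3]]$values)
  expect_error(subsample_variations(bm$data, "ks", 0.05, 2, seed = 1),
               "fewer than 2 cells")
})

test_that("window problems stack replicate rows faithfully", {
  bm <- make_benchmark(n_genes = 4, n_cells = 25, seed = 17)
  vars <- subsample_variations(bm$data, "ks", 0.8, 6, seed = 3)
  nint <- nrow(vars[[1]]$values)
  expect_equal(nint, 7)
  for (k in c(1, 4, nint - 1)) {
    prob <- build_window_problems(vars, k)
    expect_equal(nrow(prob$design), 6)
    for (r in 1:6) {
      expect_equal(prob$design[r, ], vars[[r]]$values[k, ])
      expect_equal(prob$responses[r, ], vars[[r]]$values[k + 1, ])
    }
    expect_equal(prob$exclude, 1:4)
  }
  expect_error(build_window_problems(vars, nint), "window_index")
  expect_warning(build_window_problems(vars[1], 1), "under-determined")
})

test_that("two-gene partial correlation equals plain Spearman correlation", {
  set.seed(41)
  x <- cbind(a = rnorm(200), b = rnorm(200))
  x[, 2] <- x[, 2] + 0.6 * x[, 1]
  p <- spearman_partial_cor(x)
  expect_equal(p[1, 2], cor(x[, 1], x[, 2], method = "spearman"),
               tolerance = 1e-10)
  expect_equal(diag(p), c(a = 1, b = 1))
})

test_that("partial correlation separates direct from mediated association", {
  set.seed(42)
  n <- 2000
  x <- rnorm(n)
  y <- x + rnorm(n, sd = 0.5)
  z <- y + rnorm(n, sd = 0.5)
  p <- spearman_partial_cor(cbind(x = x, y = y, z = z))
  expect_lt(abs(p["x", "z"]), 0.1)
  expect_gt(p["x", "y"], 0.5)
  expect_gt(p["y", "z"], 0.5)
  # matches the regression-residual definition
  expect_equal(p["x", "y"], oracle_partial_cor(cbind(x, y, z), 1, 2),
               tolerance = 1e-6)
  expect_equal(p["x", "z"], oracle_partial_cor(cbind(x, y, z), 1, 3),
               tolerance = 1e-6)
  # independent variables show no association
  w <- matrix(rnorm(3 * 2000), ncol = 3)
  pw <- spearman_partial_cor(w)
  expect_true(all(abs(pw[upper.tri(pw)]) < 0.1))
})

test_that("constant columns get zero partial correlations with a warning", {
  set.seed(43)
  x <- cbind(rnorm(100), rep(2, 100), rnorm(100))
  expect_warning(p <- spearman_partial_cor(x), "constant")
  expect_true(all(p[2, -2] == 0) && all(p[-2, 2] == 0))
  expect_equal(diag(p), rep(1, 3))
})

test_that("sign matrix maps partial correlations to -1/0/+1", {
  p <- matrix(c(1, 0.3, -0.2, 0.3, 1, 1e-15, -0.2, 1e-15, 1), 3, 3)
  s <- sign_matrix(p)
  expect_equal(s[1, 2], 1)
  expect_equal(s[1, 3], -1)
  expect_equal(s[2, 3], 0)
})

test_that("negating one gene's expression flips its partial-correlation signs", {
  set.seed(44)
  x <- matrix(rnorm(200 * 4), 200, 4)
  x[, 2] <- x[, 1] + rnorm(200, sd = 0.4)
  x[, 3] <- -x[, 1] + rnorm(200, sd = 0.4)
  s1 <- sign_matrix(spearman_partial_cor(x))
  xf <- x
  xf[, 1] <- -xf[, 1]
  s2 <- sign_matrix(spearman_partial_cor(xf))
  expect_equal(s2[1, -1], -s1[1, -1])
  expect_equal(s2[-1, -1], s1[-1, -1])
})

test_that("the pipeline yields T-2 windows with zero diagonals, reproducibly", {
  bm <- make_benchmark(n_genes = 5, n_cells = 30, seed = 51)
  fit <- fdygrn(bm$data, measure = "js", penalty = "mcp",
                n_replicates = 8, n_folds = 4, seed = 3)
  expect_s3_class(fit, "fdygrn")
  expect_length(fit$windows, length(bm$data$times) - 2)
  for (w in fit$windows) {
    expect_true(all(diag(w$alpha) == 0))
    expect_true(all(diag(w$adjacency) == 0))
    expect_equal(w$adjacency, w$alpha * w$sign)
    expect_true(all(w$sign %in% c(-1, 0, 1)))
    expect_equal(w$sign, t(w$sign))
  }
  fit2 <- fdygrn(bm$data, measure = "js", penalty = "mcp",
                 n_replicates = 8, n_folds = 4, seed = 3)
  fit2$call <- fit$call
  expect_identical(fit, fit2)
})

test_that("adjacency support is the intersection of alpha and sign support", {
  bm <- make_benchmark(n_genes = 4, n_cells = 25, seed = 52)
  fit <- fdygrn(bm$data, measure = "ks", penalty = "lasso",
                n_replicates = 6, n_folds = 3, seed = 1)
  for (w in fit$windows) {
    off <- !diag(4)
    expect_equal((w$adjacency != 0)[off],
                 ((w$alpha != 0) & (w$sign != 0))[off])
  }
})

test_that("pipeline configuration defaults mirror the sampling protocol", {
  expect_equal(formals(fdygrn)$fraction, 0.8)
  expect_equal(formals(fdygrn)$n_replicates, 100L)
  expect_equal(formals(fdygrn)$n_folds, 10L)
  expect_equal(formals(subsample_variations)$fraction, 0.8)
  expect_equal(formals(subsample_variations)$n_replicates, 100L)
  expect_equal(formals(cv_select_lambda)$n_folds, 10L)
})

test_that("end-to-end recovery beats the static-competitor AUROC band", {
  # strong kinetics (half-saturation at the operating point), low noise
  net <- random_grn(10, 0.15, seed = 2)
  data <- simulate_sde(net, n_cells = 100, K = 5, sigma = 0.05, seed = 2)
  aucs <- vapply(1:2, function(i) {
    fit <- fdygrn(data, measure = "js", penalty = "mcp",
                  n_replicates = 25, seed = 50 * i)
    evaluate_run(fit, net)$mean_auroc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
})

test_that("summary and coef expose the fitted networks", {
  bm <- make_benchmark(n_genes = 4, n_cells = 25, seed = 53)
  fit <- fdygrn(bm$data, n_replicates = 6, n_folds = 3, seed = 2)
  s <- summary(fit)
  expect_equal(s$n_windows, 6)
  expect_length(coef(fit), 6)
  expect_equal(coef(fit, 2), fit$windows[[2]]$adjacency)
  expect_output(print(fit), "6 windows")
})
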