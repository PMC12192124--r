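test_that("the unpenalized fit recovers ordinary least squares", {
  set.seed(1)
  X <- matrix(rnorm(200), 50, 4)
  y <- drop(X %*% c(1, -2, 0, 0.5)) + rnorm(50, sd = 0.1)
  for (kind in c("lasso", "scad", "mcp")) {
    f <- fit_penalized_var(X, y, penalty_spec(kind, 0))
    ols <- coef(lm(y ~ X))
    expect_equal(f$alpha, unname(ols[-1]), tolerance = 1e-6)
    expect_lt(abs(f$intercept - unname(ols[1])), 1e-6)
  }
})

test_that("lambda at the KKT bound zeroes every coefficient", {
  set.seed(2)
  X <- matrix(rnorm(300), 60, 5)
  y <- drop(X %*% c(2, 0, -1, 0, 0)) + rnorm(60, sd = 0.5)
  std <- fdygrn:::standardize_cols(X)
  lmax <- max(abs(crossprod(std$xs, y - mean(y)) / 60))
  for (kind in c("lasso", "scad", "mcp")) {
    f <- fit_penalized_var(X, y, penalty_spec(kind, lmax * 1.0001))
    expect_true(all(f$alpha == 0))
    f2 <- fit_penalized_var(X, y, penalty_spec(kind, lmax * 0.5))
    expect_gt(sum(f2$alpha != 0), 0)
  }
})

test_that("an orthonormal design reduces the lasso to soft-thresholding", {
  set.seed(3)
  n <- 64; m <- 5
  Q <- qr.Q(qr(scale(matrix(rnorm(n * m), n, m), scale = FALSE)))
  X <- Q * sqrt(n)  # mean-0 columns, unit population variance, Gram = I
  y <- drop(X %*% c(1.5, -0.8, 0.05, 0, 2)) + rnorm(n, sd = 0.2)
  lam <- 0.3
  f <- fit_penalized_var(X, y, penalty_spec("lasso", lam))
  z <- drop(crossprod(X, y - mean(y))) / n
  soft <- sign(z) * pmax(abs(z) - lam, 0)
  expect_equal(f$alpha, soft, tolerance = 1e-6)
})

test_that("the excluded predictor stays exactly zero", {
  set.seed(4)
  X <- matrix(rnorm(400), 80, 5)
  y <- drop(X %*% c(3, 1, 0, 0, 0)) + rnorm(80, sd = 0.1)
  f <- fit_penalized_var(X, y, penalty_spec("mcp", 0.01), exclude = 1)
  expect_identical(f$alpha[1], 0)
  expect_gt(sum(f$alpha != 0), 0)
})

test_that("coordinate descent descends the lasso objective sweep by sweep", {
  set.seed(5)
  n <- 40; m <- 8
  X <- matrix(rnorm(n * m), n, m)
  y <- rnorm(n)
  std <- fdygrn:::standardize_cols(X)
  xs <- std$xs
  yc <- y - mean(y)
  gram <- crossprod(xs) / n
  xty <- drop(crossprod(xs, yc)) / n
  lam <- 0.05
  objective <- function(kind, beta)
    sum((yc - xs %*% beta)^2) / (2 * n) +
      sum(penalty_value(penalty_spec(kind, lam, 3), beta))
  obj_after <- function(kind, sweeps)
    objective(kind, drop(fdygrn:::solve_path(gram, xty, lam, kind, 3,
      tol = 0, max_iter = sweeps, warn = FALSE)$beta))
  objs <- vapply(1:6, function(k) obj_after("lasso", k), numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
  # nonconvex penalties: converged objective no worse than the zero start
  for (kind in c("scad", "mcp")) {
    spec <- penalty_spec(kind, lam, 3)
    f <- fit_penalized_var(X, y, spec)
    beta_std <- f$alpha * std$scale
    expect_lte(objective(kind, beta_std), objective(kind, rep(0, m)))
  }
})

test_that("the lasso path agrees with glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(6)
  X <- matrix(rnorm(500), 100, 5)
  y <- drop(X %*% c(1, -1, 0.5, 0, 0)) + rnorm(100, sd = 0.3)
  lam <- 0.08
  f <- fit_penalized_var(X, y, penalty_spec("lasso", lam))
  g <- glmnet::glmnet(X, y, lambda = c(0.5, 0.2, lam), standardize = TRUE,
                      thresh = 1e-12)
  gc <- as.numeric(coef(g, s = lam, exact = FALSE))
  expect_equal(f$alpha, gc[-1], tolerance = 1e-3)
  expect_equal(f$intercept, gc[1], tolerance = 1e-3)
})

test_that("cross-validation recovers a planted signal", {
  set.seed(7)
  X <- matrix(rnorm(50 * 6), 50, 6)
  y <- 2 * X[, 3] + rnorm(50, sd = 0.01)
  for (kind in c("lasso", "mcp")) {
    cv <- cv_select_lambda(X, y, penalty_spec(kind), seed = 7)
    expect_true(cv$fit$alpha[3] != 0)
    expect_equal(length(cv$lambda), 100)
    expect_equal(max(cv$fold), 10)
  }
})

test_that("cross-validation keeps the null model sparse on pure noise", {
  hits <- vapply(1:50, function(s) {
    X <- withr::with_seed(s, matrix(rnorm(50 * 6), 50, 6))
    y <- withr::with_seed(1000 + s, rnorm(50))
    cv <- cv_select_lambda(X, y, penalty_spec("lasso"), seed = s)
    sum(cv$fit$alpha != 0) <= 2
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("fold counts shrink with a warning when blocks are scarce", {
  set.seed(8)
  X <- matrix(rnorm(6 * 4), 6, 4)
  y <- rnorm(6)
  expect_warning(cv <- cv_select_lambda(X, y, penalty_spec("lasso"),
                                        n_folds = 10, seed = 1),
                 "reducing folds")
  expect_equal(max(cv$fold), 6)
})

test_that("shrinkage ordering: MCP debiases large coefficients relative to the lasso", {
  set.seed(9)
  X <- matrix(rnorm(100 * 6), 100, 6)
  y <- drop(X %*% c(2, -1.5, 1, 0, 0, 0)) + rnorm(100, sd = 0.2)
  lam <- 0.1
  fl <- fit_penalized_var(X, y, penalty_spec("lasso", lam))
  fm <- fit_penalized_var(X, y, penalty_spec("mcp", lam, 3))
  both <- which(fl$alpha != 0 & fm$alpha != 0)
  expect_gt(length(both), 0)
  expect_true(all(abs(fl$alpha[both]) <= abs(fm$alpha[both]) + 1e-8))
})

test_that("support recovery meets the F1 bar on sparse VAR-style problems", {
  f1_one <- function(kind, seed) {
    withr::with_seed(seed, {
      m <- 10; n <- 100
      X <- matrix(rnorm(n * m), n, m)
      supp <- sample(m, 3)
      b <- numeric(m)
      b[supp] <- sample(c(-1, 1), 3, TRUE) * runif(3, 0.5, 1.5)
      sig <- drop(X %*% b)
      y <- sig + rnorm(n, sd = sqrt(var(sig) / 10))  # SNR 10
      cv <- cv_select_lambda(X, y, penalty_spec(kind), seed = seed)
      est <- which(cv$fit$alpha != 0)
      tp <- length(intersect(est, supp))
      if (tp == 0) return(0)
      pr <- tp / length(est); rc <- tp / 3
      2 * pr * rc / (pr + rc)
    })
  }
  for (kind in c("lasso", "scad", "mcp")) {
    f1 <- mean(vapply(1:20, function(s) f1_one(kind, s), numeric(1)))
    expect_gte(f1, 0.7)
  }
})
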