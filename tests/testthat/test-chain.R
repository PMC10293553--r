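test_that("unpenalized ridge recovers exact linear coefficients", {
  set.seed(1)
  X <- matrix(rnorm(200 * 6), 200, 6)
  beta <- c(2, -1, 0.5, 0, 3, -0.25)
  y <- drop(X %*% beta) + 1.5
  fit <- fit_base_linear(X, y, base = "ridge", alpha = 0)
  expect_equal(fit$coefficients, beta, tolerance = 1e-8)
  expect_equal(fit$intercept, 1.5, tolerance = 1e-8)
})

test_that("extreme L1 shrinkage collapses to the intercept-only model", {
  set.seed(2)
  X <- scale(matrix(rnorm(100 * 5), 100, 5))
  y <- rnorm(100, mean = 4)
  fit <- fit_base_linear(X, y, base = "lasso", alpha = 1e6)
  expect_equal(fit$coefficients, rep(0, 5))
  expect_equal(fit$intercept, mean(y), tolerance = 1e-10)
})

test_that("elastic net at gamma = 1 coincides with the lasso", {
  set.seed(3)
  X <- matrix(rnorm(80 * 7), 80, 7)
  y <- drop(X %*% rnorm(7)) + rnorm(80, sd = 0.3)
  l <- fit_base_linear(X, y, base = "lasso", alpha = 0.05)
  e <- fit_base_linear(X, y, base = "elasticnet", alpha = 0.05, gamma = 1)
  expect_equal(e$coefficients, l$coefficients, tolerance = 1e-9)
  expect_error(fit_base_linear(X, y, alpha = -1), "alpha")
  Xb <- X; Xb[1, 1] <- NA
  expect_error(fit_base_linear(Xb, y), "finite")
})

test_that("coordinate descent is KKT-optimal and dominates independent solutions", {
  skip_if_not_installed("glmnet")
  enet_obj <- function(X, y, w, b0, alpha, gamma) {
    n <- length(y)
    r <- y - b0 - drop(X %*% w)
    sum(r^2) / (2 * n) + gamma * alpha * sum(abs(w)) +
      alpha * (1 - gamma) / 2 * sum(w^2)
  }
  set.seed(4)
  for (rep in 1:50) {
    X <- matrix(rnorm(40 * 8), 40, 8)
    y <- drop(X %*% rnorm(8, sd = 0.7)) + rnorm(40, sd = 0.5)
    alpha <- 10^runif(1, -3, -0.5)
    gamma <- sample(c(0.4, 0.7, 1), 1)
    ours <- fit_base_linear(X, y, base = "elasticnet", alpha = alpha,
                            gamma = gamma, tol = 1e-12)
    w <- ours$coefficients
    # subgradient optimality certificate of the fitted coefficients
    Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
    grad <- -drop(crossprod(Xc, yc - Xc %*% w)) / nrow(X) +
      alpha * (1 - gamma) * w
    l1 <- alpha * gamma
    nz <- w != 0
    if (any(nz)) expect_lt(max(abs(grad[nz] + l1 * sign(w[nz]))), 1e-8)
    if (any(!nz)) expect_lte(max(abs(grad[!nz])), l1 + 1e-8)
    # the CD solution is at least as good as an independent solver's
    gn <- glmnet::glmnet(X, y, alpha = gamma, lambda = alpha,
                         standardize = FALSE, thresh = 1e-14)
    f_ours <- enet_obj(X, y, w, ours$intercept, alpha, gamma)
    f_ref <- enet_obj(X, y, as.numeric(gn$beta), as.numeric(gn$a0),
                      alpha, gamma)
    expect_lte(f_ours, f_ref + 1e-5)
    if (gamma == 1)  # pure lasso: the two solvers coincide tightly
      expect_equal(w, as.numeric(gn$beta), tolerance = 1e-6)
    # ... and no worse than the ridge solution under the same penalty budget
    ridge <- fit_base_linear(X, y, base = "ridge",
                             alpha = alpha * nrow(X) * gamma)
    f_ridge <- enet_obj(X, y, ridge$coefficients, ridge$intercept, alpha,
                        gamma)
    expect_lte(f_ours, f_ridge + 1e-12)
  }
})

# Forward-simulated sequential linear process: y_1 = f(X), y_i = f(X, y_{i-1}).
make_chain_process <- function(n = 120, p = 13, k = 8, seed = 5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  Y <- matrix(0, n, k)
  Y[, 1] <- drop(X %*% rnorm(p, sd = 0.4)) + 0.3
  for (i in 2:k)
    Y[, i] <- 0.8 * Y[, i - 1] + drop(X[, 1:3] %*% rnorm(3, sd = 0.2)) + 0.1
  colnames(Y) <- paste0("F", 1:k)
  d <- as.data.frame(cbind(X, Y))
  attr(d, "feature_cols") <- paste0("x", 1:p)
  attr(d, "target_cols") <- paste0("F", 1:k)
  d
}

test_that("a noise-free sequential process is reproduced by the chain", {
  d <- make_chain_process()
  fit <- dpk_chain(d, base = "ridge", alpha = 0)
  pred <- predict(fit, d, clip = FALSE)
  Y <- as.matrix(d[, attr(d, "target_cols")])
  expect_lt(max(abs(pred - Y)), 1e-6)
  # per-target least-squares oracle agrees on the observed-input design
  X <- as.matrix(d[, attr(d, "feature_cols")])
  for (i in c(1, 4, 8)) {
    D <- if (i == 1) X else cbind(X, Y[, 1:(i - 1)])
    ls <- stats::lm.fit(cbind(1, D), Y[, i])
    expect_lt(max(abs(ls$residuals)), 1e-8)
  }
})

test_that("chain structure: degenerate k = 1 and input dimensionality", {
  d <- noiseless_dataset()
  d1 <- d[, c(attr(d, "feature_cols"), "F1")]
  attr(d1, "feature_cols") <- attr(d, "feature_cols")
  attr(d1, "target_cols") <- "F1"
  fit1 <- dpk_chain(d1, base = "ridge", alpha = 0.1)
  Xf <- as.matrix(d[, attr(d, "feature_cols")])
  ctr <- colMeans(Xf)
  scl <- apply(Xf, 2, sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(Xf, 2, ctr), 2, scl, "/")
  single <- fit_base_linear(Xs, d$F1, base = "ridge", alpha = 0.1)
  expect_equal(fit1$models[[1]]$coefficients, single$coefficients,
               tolerance = 1e-6)
  fit <- dpk_chain(d, base = "ridge", alpha = 0.1)
  expect_length(fit$models[[60]]$coefficients, 13 + 59)
  expect_length(fit$models[[1]]$coefficients, 13)
})

test_that("predictions are deterministic, 60 wide, non-negative, order-checked", {
  d <- noiseless_dataset()
  fit <- dpk_chain(d, base = "ridge", alpha = 0.01)
  p1 <- predict(fit, d)
  p2 <- predict(fit, d)
  expect_identical(p1, p2)
  expect_equal(ncol(p1), 60)
  expect_true(all(p1 >= 0))
  expect_error(predict(fit, as.matrix(d[, attr(d, "target_cols")])),
               "columns")
  expect_error(predict(fit, d[, -(2:3)]), "lacks feature columns")
})

test_that("ridge chains are invariant to training-row order", {
  d <- noiseless_dataset()
  fit_a <- dpk_chain(d, base = "ridge", alpha = 0.05)
  set.seed(11)
  perm <- sample(nrow(d))
  dp <- d[perm, ]
  attr(dp, "feature_cols") <- attr(d, "feature_cols")
  attr(dp, "target_cols") <- attr(d, "target_cols")
  fit_b <- dpk_chain(dp, base = "ridge", alpha = 0.05)
  expect_equal(predict(fit_a, d), predict(fit_b, d), tolerance = 1e-10)
})

test_that("tuned ridge recovers the noiseless emulator kernels (R^2 >= 0.95)", {
  d <- noiseless_dataset()
  fit <- dpk_chain(d, base = "ridge", seed = 2)
  m <- regression_metrics(as.matrix(d[, attr(d, "target_cols")]),
                          predict(fit, d))
  expect_gte(m$r2, 0.95)
})

test_that("metrics match their closed-form cases", {
  set.seed(6)
  Y <- matrix(abs(rnorm(50 * 4)) + 0.1, 50, 4)
  m_id <- regression_metrics(Y, Y)
  expect_equal(m_id$r2, 1)
  expect_equal(m_id$rmse, 0)
  expect_equal(m_id$mape, 0)
  m_mean <- regression_metrics(Y, matrix(mean(Y), 50, 4))
  expect_equal(m_mean$r2, 0, tolerance = 1e-12)
  m_10 <- regression_metrics(Y, 1.1 * Y)
  expect_equal(m_10$mape, 10, tolerance = 1e-10)
  expect_error(regression_metrics(Y, Y[1:10, ]), "shape")
  expect_error(regression_metrics(matrix(0, 3, 2), matrix(1, 3, 2)), "zero")
})

test_that("chain models survive a JSON round trip exactly", {
  d <- noiseless_dataset()
  fit <- dpk_chain(d, base = "lasso", alpha = 1e-3)
  path <- withr::local_tempfile(fileext = ".json")
  write_dpk_chain(fit, path)
  fit2 <- read_dpk_chain(path)
  expect_equal(predict(fit2, d), predict(fit, d), tolerance = 1e-12)
  expect_identical(fit2$base, "lasso")
  expect_error(read_dpk_chain(withr::local_tempfile(lines = "{}",
                                                    fileext = ".json")),
               "model file")
})
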