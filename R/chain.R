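# Multi-target regressor chain for scaled dose point kernels.
#
# The chain is an ordered sequence of k regularized linear models: model i is
# trained on the original features augmented with the observed targets
# y_1..y_{i-1}, and at prediction time receives the cascaded predictions
# yhat_1..yhat_{i-1}. Base objectives:
#   ridge       : min_w ||Xw - y||_2^2 + alpha ||w||_2^2        (closed form)
#   lasso       : min_w 1/(2n) ||Xw - y||_2^2 + alpha ||w||_1
#   elastic net : min_w 1/(2n) ||Xw - y||_2^2 + gamma alpha ||w||_1
#                       + alpha (1 - gamma)/2 ||w||_2^2
# The quadratic term of the L1-penalized objectives carries the 1/(2n)
# normalization so that gamma = 1 reduces the elastic net exactly to the
# lasso. Intercepts are never penalized (handled by centering).

.soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# Cyclic coordinate descent on the elastic-net objective with covariance
# updates (O(p) per coordinate; inner loop compiled, see src/enet_cd.cpp).
# X, y are expected centered; returns the coefficient vector. Coefficients
# start at `w0` (zeros by default).
.enet_cd <- function(X, y, alpha, gamma, tol = 1e-6, max_sweeps = 1e4,
                     w0 = NULL) {
  n <- nrow(X); p <- ncol(X)
  S <- crossprod(X) / n
  cvec <- drop(crossprod(X, y)) / n
  w <- if (is.null(w0)) numeric(p) else w0
  .enet_cd_cov(S, cvec, w, gamma * alpha, alpha * (1 - gamma),
               tol, as.integer(max_sweeps))
}

# Ridge normal equations solved through the SVD; at alpha = 0 this is the
# minimum-norm least-squares solution, which keeps exactly collinear chain
# designs (targets that are linear in earlier targets) well defined.
.ridge_solve <- function(X, y, alpha) {
  sv <- svd(X)
  d <- sv$d
  f <- if (alpha == 0) ifelse(d > max(d, 0) * 1e-10, 1 / d, 0)
       else d / (d^2 + alpha)
  drop(sv$v %*% (f * crossprod(sv$u, y)))
}

#' Fit one regularized linear base model
#'
#' Fits a single target with one of the three base objectives. The intercept
#' is never penalized: columns and response are centered internally and the
#' intercept recovered from the means. Ridge is solved in closed form via the
#' normal equations; lasso and elastic net by cyclic coordinate descent
#' (convergence when the largest coefficient update falls below `tol`, or
#' after `max_sweeps` sweeps).
#'
#' @param X Numeric matrix of predictors (rows = samples).
#' @param y Numeric response vector.
#' @param base `"ridge"`, `"lasso"`, or `"elasticnet"`.
#' @param alpha Regularization strength (>= 0).
#' @param gamma L1 mixing in \[0, 1\] (elastic net; `gamma = 1` is the lasso,
#'   `gamma = 0` the ridge objective up to the 1/(2n) scaling).
#' @param tol,max_sweeps Coordinate-descent stopping rule.
#' @return List with `coefficients`, `intercept`, `base`, `alpha`, `gamma`.
#' @export
fit_base_linear <- function(X, y, base = c("ridge", "lasso", "elasticnet"),
                            alpha = 0, gamma = 0.5, tol = 1e-6,
                            max_sweeps = 1e4) {
  base <- match.arg(base)
  X <- as.matrix(X)
  if (!is.numeric(X) || !all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in X or y")
  if (nrow(X) != length(y) || length(y) < 2) stop("need nrow(X) == length(y) >= 2")
  if (alpha < 0) stop("alpha must be >= 0")
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  gam <- switch(base, ridge = NA_real_, lasso = 1, elasticnet = gamma)
  w <- if (base == "ridge") .ridge_solve(Xc, yc, alpha)
       else .enet_cd(Xc, yc, alpha, gam, tol = tol, max_sweeps = max_sweeps)
  list(coefficients = w, intercept = ym - sum(xm * w),
       base = base, alpha = alpha, gamma = gam)
}

.target_cols <- function(dataset) {
  tc <- attr(dataset, "target_cols")
  if (is.null(tc)) {
    tc <- grep("^F[0-9]+$", names(dataset), value = TRUE)
    tc <- tc[order(as.integer(sub("^F", "", tc)))]
  }
  tc
}

.feature_cols <- function(dataset) {
  fc <- attr(dataset, "feature_cols")
  if (is.null(fc)) fc <- intersect(DPK_FEATURES, names(dataset))
  fc
}

# Fit the full chain on standardized inputs. Returns the per-target models
# plus the standardization state shared with prediction.
.fit_chain_raw <- function(X, Y, base, alpha, gamma, standardize) {
  k <- ncol(Y)
  ctr <- colMeans(cbind(X, Y))
  scl <- apply(cbind(X, Y), 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  if (!standardize) { ctr[] <- 0; scl[] <- 1 }
  p <- ncol(X)
  Xs <- sweep(sweep(X, 2, ctr[seq_len(p)]), 2, scl[seq_len(p)], "/")
  Ys <- sweep(sweep(Y, 2, ctr[p + seq_len(k)]), 2, scl[p + seq_len(k)], "/")
  models <- vector("list", k)
  for (i in seq_len(k)) {
    D <- if (i == 1) Xs else cbind(Xs, Ys[, seq_len(i - 1), drop = FALSE])
    models[[i]] <- fit_base_linear(D, Y[, i], base = base, alpha = alpha,
                                   gamma = gamma)
  }
  list(models = models, center = ctr, scale = scl)
}

.predict_chain_raw <- function(fit, X, k) {
  p <- ncol(X)
  ctr <- fit$center; scl <- fit$scale
  Xs <- sweep(sweep(X, 2, ctr[seq_len(p)]), 2, scl[seq_len(p)], "/")
  n <- nrow(X)
  Yhat <- matrix(0, n, k)
  D <- Xs
  for (i in seq_len(k)) {
    m <- fit$models[[i]]
    Yhat[, i] <- drop(D %*% m$coefficients) + m$intercept
    if (i < k) {
      yin <- (Yhat[, i] - ctr[p + i]) / scl[p + i]
      D <- cbind(D, yin)
    }
  }
  Yhat
}

#' Fit a regressor chain for scaled dose point kernels
#'
#' Trains an ordered chain of `k` regularized linear models on a dataset of
#' per-shell kernel values (one row per material/energy pair, as produced by
#' [generate_dataset()]). Model `i` is fitted on the 13 features plus the
#' observed targets `F1..F(i-1)`; at prediction time the chain cascades its
#' own predictions. Features (and targets when used as chain inputs) are
#' z-scored with training statistics; targets themselves are fitted unscaled.
#'
#' When `alpha` is `NULL`, hyperparameters are selected on a seeded 20%
#' validation split by pooled RMSE over a log grid of `alpha` (and, for the
#' elastic net, a small grid of `gamma`), then the chain is refitted on all
#' rows with the selected values.
#'
#' @param dataset Data frame with the 13 feature columns and targets
#'   `F1..Fk` (attributes `feature_cols`/`target_cols` honored).
#' @param base Base objective: `"ridge"`, `"lasso"`, or `"elasticnet"`.
#' @param alpha Regularization strength; `NULL` for grid search.
#' @param gamma Elastic-net L1 mixing; `NULL` for grid search.
#' @param standardize Z-score inputs with training statistics (default TRUE).
#' @param seed Integer seed controlling the validation split.
#' @param alpha_grid,gamma_grid Candidate grids for the search.
#' @param validation_fraction Fraction of rows held out for selection.
#' @return Object of class `dpk_chain` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, and `residuals` methods.
#' @examples
#' d <- generate_dataset(c("HU18", "HU200"), c(50, 100, 500, 1000),
#'                       n_primaries = Inf, seed = 1)
#' fit <- dpk_chain(d, base = "ridge", alpha = 1e-4)
#' summary(fit)
#' @export
dpk_chain <- function(dataset, base = c("ridge", "lasso", "elasticnet"),
                      alpha = NULL, gamma = NULL, standardize = TRUE,
                      seed = 1L,
                      alpha_grid = 10^seq(-4, 1, length.out = 6),
                      gamma_grid = c(0.25, 0.5, 0.75),
                      validation_fraction = 0.2) {
  base <- match.arg(base)
  fc <- .feature_cols(dataset)
  tc <- .target_cols(dataset)
  if (length(tc) < 1) stop("dataset has no target columns (F1, F2, ...)")
  X <- as.matrix(dataset[, fc, drop = FALSE])
  Y <- as.matrix(dataset[, tc, drop = FALSE])
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  tuning <- NULL
  if (is.null(alpha)) {
    grid <- if (base == "elasticnet") {
      if (is.null(gamma)) expand.grid(alpha = alpha_grid, gamma = gamma_grid)
      else expand.grid(alpha = alpha_grid, gamma = gamma)
    } else data.frame(alpha = alpha_grid, gamma = if (base == "lasso") 1 else 0)
    n <- nrow(X)
    idx_val <- .with_seed(seed,
                          sample.int(n, max(1L, floor(validation_fraction * n))))
    rmse <- apply(grid, 1, function(g) {
      f <- .fit_chain_raw(X[-idx_val, , drop = FALSE],
                          Y[-idx_val, , drop = FALSE],
                          base, g[["alpha"]], g[["gamma"]], standardize)
      yh <- .predict_chain_raw(f, X[idx_val, , drop = FALSE], length(tc))
      sqrt(mean((Y[idx_val, , drop = FALSE] - yh)^2))
    })
    best <- which.min(rmse)
    alpha <- grid$alpha[best]
    gamma <- grid$gamma[best]
    tuning <- cbind(grid, rmse = rmse)
  }
  if (is.null(gamma)) gamma <- 0.5
  fit <- .fit_chain_raw(X, Y, base, alpha, gamma, standardize)
  yhat_train <- .predict_chain_raw(fit, X, length(tc))
  structure(list(
    base = base, alpha = alpha, gamma = if (base == "elasticnet") gamma else
      switch(base, lasso = 1, ridge = NA_real_),
    standardize = standardize, seed = as.integer(seed),
    feature_names = fc, target_names = tc, k = length(tc),
    models = fit$models, center = fit$center, scale = fit$scale,
    tuning = tuning,
    training = list(y = Y, fitted = yhat_train,
                    metrics = regression_metrics(Y, yhat_train))
  ), class = "dpk_chain")
}

#' Predict scaled DPKs from a fitted chain
#'
#' Cascades the chain: model 1 sees the features, model `i` additionally sees
#' the predictions for targets `1..i-1`. Prediction is deterministic.
#' Negative values are clipped to zero at the end (physical non-negativity of
#' the kernels) unless `clip = FALSE`.
#'
#' @param object A `dpk_chain`.
#' @param newdata Data frame (or matrix) containing the fitted feature
#'   columns, in any order for data frames; matrices must match the fitted
#'   column order.
#' @param clip Clip negative predictions to zero (default TRUE).
#' @param ... Unused.
#' @return Numeric matrix, one row per input row, `k` kernel values per row.
#' @export
predict.dpk_chain <- function(object, newdata, clip = TRUE, ...) {
  if (is.data.frame(newdata)) {
    missing <- setdiff(object$feature_names, names(newdata))
    if (length(missing))
      stop("newdata lacks feature columns: ", paste(missing, collapse = ", "))
    X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  } else {
    X <- as.matrix(newdata)
    if (ncol(X) != length(object$feature_names))
      stop("newdata must have ", length(object$feature_names), " columns in ",
           "the fitted order: ", paste(object$feature_names, collapse = ", "))
  }
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite feature values")
  Yhat <- .predict_chain_raw(object[c("models", "center", "scale")], X,
                             object$k)
  colnames(Yhat) <- object$target_names
  if (clip) Yhat[Yhat < 0] <- 0
  Yhat
}

#' Predict a scaled DPK for a material and energies
#'
#' Convenience wrapper building the feature vector (energy, areal range,
#' density, weight fractions) for each requested energy and returning `sdpk`
#' objects on the 60-shell monoenergetic grid.
#'
#' @param object A fitted `dpk_chain`.
#' @param material A `dpk_material` or label.
#' @param energies Energies in keV.
#' @param range_table Optional range-table override (see [csda_range()]).
#' @return A list of `sdpk`, one per energy.
#' @export
predict_sdpk <- function(object, material, energies, range_table = NULL) {
  if (is.character(material)) material <- material_lookup(material)
  feats <- dpk_features(material, energies, range_table = range_table)
  Yhat <- predict(object, feats)
  grid <- shell_grid(object$k, 1 / 40)
  lapply(seq_along(energies), function(i) {
    new_sdpk(grid, Yhat[i, ], energy0 = energies[i],
             material_label = material$label, scale = "rcsda")
  })
}

#' Build the model feature table for a material at given energies
#' @inheritParams predict_sdpk
#' @return Data frame with the 13 feature columns in model order.
#' @export
dpk_features <- function(material, energies, range_table = NULL) {
  if (is.character(material)) material <- material_lookup(material)
  r0 <- csda_range(energies, material, range_table = range_table)$r0_areal
  out <- data.frame(E0_keV = energies, R_CSDA_g_cm2 = r0,
                    density = material$density)
  w <- material$weights[c("H", "C", "Na", "Mg", "P", "S", "Cl", "Ar", "K",
                          "Ca")]
  for (j in seq_along(w)) out[[paste0("w_", names(w)[j])]] <- w[[j]]
  out
}

#' Regression metrics for multi-target kernel predictions
#'
#' Pooled coefficient of determination, root-mean-square error, and mean
#' absolute percentage error over all rows and targets, plus a per-target
#' breakdown. R^2 is computed against the pooled grand mean; MAPE is taken
#' over entries with nonzero truth only and reported in percent.
#'
#' @param y_true,y_pred Numeric matrices (or vectors) of equal shape.
#' @return Object of class `dpk_metrics`: list with `r2`, `rmse`, `mape`,
#'   and `per_target` data frame.
#' @export
regression_metrics <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) stop("shape mismatch")
  if (all(y_true == 0)) stop("all y_true are zero: MAPE undefined")
  res2 <- (y_true - y_pred)^2
  r2 <- 1 - sum(res2) / sum((y_true - mean(y_true))^2)
  rmse <- sqrt(mean(res2))
  nz <- y_true != 0
  mape <- 100 * mean(abs(y_true[nz] - y_pred[nz]) / abs(y_true[nz]))
  per_target <- data.frame(
    target = colnames(y_true) %||% paste0("y", seq_len(ncol(y_true))),
    r2 = vapply(seq_len(ncol(y_true)), function(j) {
      1 - sum(res2[, j]) / sum((y_true[, j] - mean(y_true[, j]))^2)
    }, 0),
    rmse = sqrt(colMeans(res2))
  )
  structure(list(r2 = r2, rmse = rmse, mape = mape, per_target = per_target),
            class = "dpk_metrics")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dpk_metrics <- function(x, ...) {
  cat(sprintf("R^2 = %.4f   RMSE = %.4g   MAPE = %.2f%%\n",
              x$r2, x$rmse, x$mape))
  invisible(x)
}

#' @export
print.dpk_chain <- function(x, ...) {
  cat(sprintf("<dpk_chain> %s chain of %d models (alpha = %.4g%s)\n",
              x$base, x$k, x$alpha,
              if (x$base == "elasticnet") sprintf(", gamma = %.2f", x$gamma)
              else ""))
  cat(sprintf("  features: %d [%s ...]\n", length(x$feature_names),
              paste(utils::head(x$feature_names, 3), collapse = ", ")))
  cat("  training: "); print(x$training$metrics)
  invisible(x)
}

#' @export
summary.dpk_chain <- function(object, ...) {
  nzero <- vapply(object$models,
                  function(m) sum(m$coefficients != 0), 0L)
  out <- list(base = object$base, alpha = object$alpha, gamma = object$gamma,
              k = object$k, metrics = object$training$metrics,
              nonzero_coefs = nzero, tuning = object$tuning)
  class(out) <- "summary.dpk_chain"
  out
}

#' @export
print.summary.dpk_chain <- function(x, ...) {
  cat(sprintf("Regressor chain (%s), k = %d targets\n", x$base, x$k))
  cat(sprintf("  alpha = %.4g", x$alpha))
  if (x$base == "elasticnet") cat(sprintf(", gamma = %.2f", x$gamma))
  cat("\n  pooled training metrics: "); print(x$metrics)
  cat(sprintf("  nonzero coefficients per model: median %d (range %d-%d)\n",
              as.integer(stats::median(x$nonzero_coefs)),
              min(x$nonzero_coefs), max(x$nonzero_coefs)))
  if (!is.null(x$tuning)) {
    best <- which.min(x$tuning$rmse)
    cat(sprintf("  tuned on validation split: best RMSE %.4g at alpha %.4g\n",
                x$tuning$rmse[best], x$tuning$alpha[best]))
  }
  invisible(x)
}

#' @export
coef.dpk_chain <- function(object, ...) {
  input_names <- c(object$feature_names, object$target_names)
  lapply(object$models, function(m) {
    stats::setNames(c(m$intercept, m$coefficients),
                    c("(Intercept)", input_names[seq_along(m$coefficients)]))
  })
}

#' @export
fitted.dpk_chain <- function(object, ...) object$training$fitted

#' @export
residuals.dpk_chain <- function(object, ...)
  object$training$y - object$training$fitted

#' Serialize a fitted chain to JSON
#'
#' Writes configuration, feature order, standardization constants, and
#' per-model coefficients/intercepts at full precision so that a reloaded
#' model reproduces predictions exactly.
#'
#' @param model A `dpk_chain`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_dpk_chain <- function(model, path) {
  stopifnot(inherits(model, "dpk_chain"))
  doc <- list(
    format = "dpkchain/chain-model", version = 1L,
    base = model$base, alpha = model$alpha, gamma = model$gamma,
    standardize = model$standardize, seed = model$seed,
    feature_names = model$feature_names, target_names = model$target_names,
    k = model$k, center = unname(model$center), scale = unname(model$scale),
    models = lapply(model$models, function(m)
      list(coefficients = unname(m$coefficients), intercept = m$intercept))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized chain model
#' @param path JSON path written by [write_dpk_chain()].
#' @return A `dpk_chain` (without training data; `fitted`/`residuals`
#'   unavailable).
#' @export
read_dpk_chain <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "dpkchain/chain-model"))
    stop("not a dpkchain model file: ", path)
  models <- if (is.data.frame(doc$models)) {
    lapply(seq_len(nrow(doc$models)), function(i)
      list(coefficients = doc$models$coefficients[[i]],
           intercept = doc$models$intercept[[i]]))
  } else {
    lapply(doc$models, function(m)
      list(coefficients = unlist(m$coefficients), intercept = m$intercept))
  }
  nm <- c(doc$feature_names, doc$target_names)
  structure(list(
    base = doc$base, alpha = doc$alpha, gamma = doc$gamma,
    standardize = doc$standardize, seed = doc$seed,
    feature_names = doc$feature_names, target_names = doc$target_names,
    k = doc$k,
    models = models,
    center = stats::setNames(doc$center, nm[seq_along(doc$center)]),
    scale = stats::setNames(doc$scale, nm[seq_along(doc$scale)]),
    tuning = NULL, training = NULL
  ), class = "dpk_chain")
}
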