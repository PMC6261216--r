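#' Gaussian radial basis kernel
#'
#' Evaluates `exp(-||x1 - x2||^2 / sigma^2)`. Note the denominator is
#' `sigma^2`, not `2 sigma^2`; `sigma` is the kernel width on the (scaled)
#' regressor space.
#'
#' @param x1,x2 Numeric vectors of equal length.
#' @param sigma Kernel width, > 0.
#' @return Kernel value in (0, 1].
#' @export
rbf_kernel <- function(x1, x2, sigma) {
  if (length(x1) != length(x2))
    stop("kernel arguments must have equal dimension")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a single positive number")
  exp(-sum((x1 - x2)^2) / sigma^2)
}

# Full Gram matrix of the RBF kernel between rows of A and rows of B.
rbf_gram <- function(A, B, sigma) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0  # numerical jitter on the diagonal
  exp(-d2 / sigma^2)
}

#' Kernel hyperparameters
#'
#' @param C Regularization parameter, > 0. Larger values penalize training
#'   residuals more (toward interpolation).
#' @param sigma RBF kernel width, > 0, on the standardized regressor scale.
#' @return A `kernel_hyperparams` object.
#' @export
kernel_hyperparams <- function(C, sigma) {
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0)
    stop("'C' must be a single positive finite number")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("'sigma' must be a single positive finite number")
  structure(list(C = C, sigma = sigma), class = "kernel_hyperparams")
}

#' Fit an LS-SVM regression model
#'
#' Least-squares support vector machine regression: equality-constrained SVM
#' whose training reduces to one symmetric linear system (the KKT
#' stationarity conditions)
#' \deqn{\begin{bmatrix} 0 & \mathbf{1}^T \\ \mathbf{1} & \Gamma + C^{-1} I
#'   \end{bmatrix} \begin{bmatrix} \delta \\ \alpha \end{bmatrix} =
#'   \begin{bmatrix} 0 \\ y \end{bmatrix}}
#' with Gram matrix `Gamma[i,j] = k(x_i, x_j)`. Regressors are standardized
#' (zero mean, unit variance per column, computed on the training set) before
#' kernel evaluation so the single width `sigma` is meaningful across
#' mixed-unit lags; the scaling is stored on the model and applied at
#' prediction time. A condition-number guard (1e12) triggers a warning and a
#' pseudoinverse least-squares solve, flagged on the model.
#'
#' @param train A `training_set` (see [make_training_set()]), N >= 2.
#' @param hyper A [kernel_hyperparams()] object.
#' @return An `lssvm` model: dual coefficients `alphas`, bias `bias`,
#'   `sigma`, `C`, standardized training inputs `X_scaled`, scaling
#'   (`center`, `scale`), lag structure, and `fallback` flag.
#' @export
fit_lssvm <- function(train, hyper) {
  stopifnot(inherits(train, "training_set"),
            inherits(hyper, "kernel_hyperparams"))
  N <- train$N
  if (N < 2L) stop("need at least 2 training samples")
  if (any(!is.finite(train$X)) || any(!is.finite(train$y)))
    stop("training set contains non-finite values")
  center <- colMeans(train$X)
  scl <- apply(train$X, 2L, stats::sd)
  scl[scl == 0] <- 1  # constant column: leave centred at zero
  Xs <- sweep(sweep(train$X, 2L, center), 2L, scl, "/")
  K <- rbf_gram(Xs, Xs, hyper$sigma)
  M <- rbind(c(0, rep(1, N)),
             cbind(1, K + diag(N) / hyper$C))
  rhs <- c(0, train$y)
  fallback <- FALSE
  cond <- kappa(M, exact = FALSE)
  if (!is.finite(cond) || cond > 1e12) {
    warning(sprintf(
      "KKT system ill-conditioned (condition estimate %.3g); using least-squares pseudoinverse solve",
      cond))
    sol <- as.vector(MASS::ginv(M) %*% rhs)
    fallback <- TRUE
  } else {
    sol <- solve(M, rhs)
  }
  structure(list(alphas = sol[-1L], bias = sol[1L],
                 sigma = hyper$sigma, C = hyper$C,
                 X_scaled = Xs, center = center, scale = scl,
                 m = train$m, n = train$n, fallback = fallback),
            class = "lssvm")
}

#' @export
print.lssvm <- function(x, ...) {
  cat(sprintf(
    "<lssvm: N=%d support values, sigma=%.4g, C=%.4g, bias=%.4g%s>\n",
    length(x$alphas), x$sigma, x$C, x$bias,
    if (x$fallback) ", least-squares fallback" else ""))
  invisible(x)
}

# Standardize raw regressors with a model's stored scaling.
scale_input <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
}

#' Predict with a fitted LS-SVM model
#'
#' Evaluates the kernel expansion
#' `sum_i alpha_i exp(-||x - x_i||^2 / sigma^2) + bias`, applying the stored
#' feature scaling to `newdata` first.
#'
#' @param object An `lssvm` model.
#' @param newdata Regressor vector, or matrix with one regressor per row.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.lssvm <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    if (length(newdata) != ncol(object$X_scaled))
      stop(sprintf("regressor has dimension %d; model expects %d",
                   length(newdata), ncol(object$X_scaled)))
    newdata <- matrix(newdata, nrow = 1L)
  } else if (ncol(newdata) != ncol(object$X_scaled)) {
    stop(sprintf("regressors have dimension %d; model expects %d",
                 ncol(newdata), ncol(object$X_scaled)))
  }
  Ks <- rbf_gram(scale_input(object, newdata), object$X_scaled, object$sigma)
  as.vector(Ks %*% object$alphas) + object$bias
}

#' Mean absolute percentage error
#'
#' `mean(|y - yhat| / |y|)`. Undefined when any actual value is zero; the
#' caller must filter or shift such series.
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @return Nonnegative scalar.
#' @export
mape <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("'actual' and 'predicted' must have equal length")
  if (any(actual == 0))
    stop("MAPE undefined: 'actual' contains zero values")
  mean(abs(actual - predicted) / abs(actual))
}

#' Fit-quality metrics: RMSE and maximum absolute error
#'
#' @param actual,predicted Numeric vectors of equal length >= 1.
#' @return A `fit_metrics` list with `rmse = sqrt(mean((y - yhat)^2))` and
#'   `maxe = max(|y - yhat|)`.
#' @export
rmse_maxe <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 1L)
    stop("'actual' and 'predicted' must have equal length >= 1")
  e <- actual - predicted
  structure(list(rmse = sqrt(mean(e^2)), maxe = max(abs(e))),
            class = "fit_metrics")
}

#' Serialize / restore an LS-SVM model as JSON
#'
#' Full-precision, lossless round trip of the dual solution, kernel settings,
#' feature scaling, standardized training inputs and lag structure.
#'
#' @param model An `lssvm` model.
#' @param path File path ending in `.json`.
#' @return `write_lssvm_json` returns `path` invisibly; `read_lssvm_json`
#'   returns the restored `lssvm` model.
#' @export
write_lssvm_json <- function(model, path) {
  stopifnot(inherits(model, "lssvm"))
  obj <- list(alphas = model$alphas, bias = model$bias, sigma = model$sigma,
              C = model$C, X_scaled = model$X_scaled,
              scaling = list(center = model$center, scale = model$scale),
              lag_spec = list(m = model$m, n = model$n),
              fallback = model$fallback)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_lssvm_json
#' @export
read_lssvm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  Xs <- matrix(as.numeric(obj$X_scaled), nrow = length(obj$alphas),
               byrow = FALSE)
  structure(list(alphas = as.numeric(obj$alphas), bias = obj$bias,
                 sigma = obj$sigma, C = obj$C,
                 X_scaled = Xs,
                 center = as.numeric(obj$scaling$center),
                 scale = as.numeric(obj$scaling$scale),
                 m = as.integer(obj$lag_spec$m), n = as.integer(obj$lag_spec$n),
                 fallback = isTRUE(obj$fallback)),
            class = "lssvm")
}
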