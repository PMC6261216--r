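#' ARX model container
#'
#' Shift-operator form `A(z^-1) y(t) = B(z^-1) u(t - d) + offset` with
#' `A(z^-1) = 1 + a[1] z^-1 + ... + a[n] z^-n` and
#' `B(z^-1) = b[1] + b[2] z^-1 + ... + b[m+1] z^-m` (the leading coefficient
#' of B is free). Equivalently, the recursion
#' `y(t) = -sum_i a[i] y(t-i) + sum_j b[j] u(t-d-j+1) + offset`.
#'
#' @param a Coefficients of A beyond the leading 1 (length n >= 1).
#' @param b Coefficients of B, highest order first at lag 0 (length >= 1).
#' @param offset Constant term.
#' @param dead_time Integer input delay d >= 0 (samples).
#' @return An `arx_model` object.
#' @export
arx_model <- function(a, b, offset = 0, dead_time = 1L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || any(!is.finite(a)))
    stop("'a' must be a finite vector of length >= 1")
  if (length(b) < 1L || any(!is.finite(b)))
    stop("'b' must be a finite vector of length >= 1")
  if (!is.finite(offset)) stop("'offset' must be finite")
  dead_time <- as.integer(dead_time)
  if (dead_time < 0L) stop("'dead_time' must be >= 0")
  structure(list(a = a, b = b, offset = offset, dead_time = dead_time),
            class = "arx_model")
}

#' @export
print.arx_model <- function(x, ...) {
  cat(sprintf("<arx_model: n=%d, m=%d, dead_time=%d, offset=%.4g>\n",
              length(x$a), length(x$b) - 1L, x$dead_time, x$offset))
  cat("  a:", signif(x$a, 6), "\n  b:", signif(x$b, 6), "\n")
  invisible(x)
}

# One-step ARX recursion. u covers times up to t when dead_time = 0, up to
# t-1 when dead_time = 1 (most recent last); y covers times up to t-1.
arx_step <- function(arx, u_hist, y_hist, include_offset = TRUE) {
  n <- length(arx$a); nb <- length(arx$b); d <- arx$dead_time
  if (length(y_hist) < n)
    stop(sprintf("need %d past outputs, have %d", n, length(y_hist)))
  # u index for coefficient b[j] (j = 1..nb): time t - d - j + 1.
  lu <- length(u_hist); ly <- length(y_hist)
  acc <- if (include_offset) arx$offset else 0
  for (i in seq_len(n)) acc <- acc - arx$a[i] * y_hist[ly - i + 1L]
  for (j in seq_len(nb)) {
    # position of u(t - d - j + 1): when d = 0, u_hist's last entry is u(t)
    # itself; when d >= 1, the last entry is u(t-1).
    back <- d + j - 1L - (if (d == 0L) 0L else 1L)
    idx <- lu - back
    if (idx < 1L)
      stop(sprintf("need %d past inputs, have %d", back + 1L, lu))
    acc <- acc + arx$b[j] * u_hist[idx]
  }
  acc
}

# Simulate the ARX model forward for `steps` steps given input values
# u_future (aligned so u_future[k] is the input at forecast step k, i.e.
# u(t+k-1) for dead_time >= 1 or u(t+k) for dead_time = 0 ... see
# free_response / step_coefficients for the two call sites).
arx_forecast <- function(arx, u_hist, y_hist, u_future, steps,
                         include_offset = TRUE) {
  d <- arx$dead_time
  y <- y_hist
  u <- u_hist
  out <- numeric(steps)
  for (k in seq_len(steps)) {
    if (d == 0L) {
      u <- c(u, u_future[k])
      out[k] <- arx_step(arx, u, y, include_offset)
    } else {
      out[k] <- arx_step(arx, u, y, include_offset)
      u <- c(u, u_future[k])
    }
    y <- c(y, out[k])
  }
  out
}

#' Analytic gradient of an LS-SVM predictor
#'
#' Gradient of the kernel expansion with respect to the raw (unscaled)
#' regressor: each RBF term contributes
#' `alpha_i k(z, z_i) (-2/sigma^2) (z - z_i)` on the standardized scale,
#' chain-ruled through the stored per-feature scaling.
#'
#' @param model An `lssvm` model.
#' @param x0 Raw regressor vector at which to differentiate.
#' @return Gradient vector, same length as `x0`.
#' @export
gradient_lssvm <- function(model, x0) {
  stopifnot(inherits(model, "lssvm"))
  if (length(x0) != ncol(model$X_scaled))
    stop(sprintf("regressor has dimension %d; model expects %d",
                 length(x0), ncol(model$X_scaled)))
  z <- as.vector(scale_input(model, x0))
  diffs <- sweep(model$X_scaled, 2L, z, "-")      # z_i - z, per row
  kv <- exp(-rowSums(diffs^2) / model$sigma^2)
  g_scaled <- (2 / model$sigma^2) * colSums(model$alphas * kv * diffs)
  as.vector(g_scaled / model$scale)
}

#' Linearize an LS-SVM NARX model at an operating point
#'
#' First-order Taylor expansion of the fitted predictor
#' `f(x) ~ f(x0) + g . (x - x0)` at the current lag vector
#' `x0 = [u(t-1), ..., u(t-m), y(t-1), ..., y(t-n)]`, rewritten in
#' shift-operator ARX form: `b[j] = df/du(t-j)` (dead time 1),
#' `a[i] = -df/dy(t-i)`, and constant offset `f(x0) - g . x0`. The affine
#' model and the LS-SVM predictor agree exactly at `x0`.
#'
#' @param model An `lssvm` model fitted on regressors built with
#'   [make_training_set()] (u lags first, then y lags).
#' @param x0 Raw regressor vector (current lag vector).
#' @return An [arx_model()] with `dead_time = 1`.
#' @export
linearize_at <- function(model, x0) {
  g <- gradient_lssvm(model, x0)
  m <- model$m; n <- model$n
  f0 <- predict(model, x0)
  arx_model(a = -g[(m + 1L):(m + n)],
            b = g[seq_len(m)],
            offset = f0 - sum(g * x0),
            dead_time = 1L)
}

#' Serialize / restore an ARX model as JSON
#'
#' @param arx An `arx_model`.
#' @param path File path.
#' @return `write_arx_json` returns `path` invisibly; `read_arx_json` the
#'   restored model.
#' @export
write_arx_json <- function(arx, path) {
  stopifnot(inherits(arx, "arx_model"))
  jsonlite::write_json(list(a = arx$a, b = arx$b, offset = arx$offset,
                            dead_time = arx$dead_time),
                       path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_arx_json
#' @export
read_arx_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  arx_model(a = obj$a, b = obj$b, offset = obj$offset,
            dead_time = obj$dead_time)
}
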