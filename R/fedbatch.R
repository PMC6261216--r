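#' Fed-batch fermentation parameters
#'
#' Parameter set for the Monod-kinetics fed-batch simulator used to generate
#' fermentation-like training batches. Units follow bioreactor convention:
#' concentrations in g/L, volume in L, feed rate in L/h, time in hours.
#'
#' @param mu_max Maximum specific growth rate (1/h).
#' @param K_s Monod half-saturation constant for the substrate (g/L).
#' @param Y_xs Biomass yield on substrate (g biomass / g substrate).
#' @param s_feed Substrate concentration of the feed stream (g/L).
#' @param V0 Initial broth volume (L).
#' @param x0 Initial biomass concentration (g/L); must be below 50 g/L.
#' @param s0 Initial substrate concentration (g/L).
#' @param noise_sd Standard deviation of i.i.d. Gaussian measurement noise
#'   added to the reported biomass concentration (g/L); 0 for noiseless.
#' @param dt Sampling interval of the recorded series (h).
#'
#' @return An object of class `fedbatch_params`.
#' @export
fedbatch_params <- function(mu_max = 0.3, K_s = 0.3, Y_xs = 0.5,
                            s_feed = 200, V0 = 50, x0 = 4, s0 = 8,
                            noise_sd = 0.05, dt = 1) {
  p <- list(mu_max = mu_max, K_s = K_s, Y_xs = Y_xs, s_feed = s_feed,
            V0 = V0, x0 = x0, s0 = s0, noise_sd = noise_sd, dt = dt)
  pos <- c("mu_max", "K_s", "Y_xs", "s_feed", "V0", "x0", "s0", "dt")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm))
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || !is.finite(noise_sd) ||
      noise_sd < 0)
    stop("'noise_sd' must be a single finite number >= 0")
  if (x0 >= 50)
    stop("'x0' must be below 50 g/L (plausible biomass range)")
  structure(p, class = "fedbatch_params")
}

#' Simulate a fed-batch fermentation batch
#'
#' Integrates Monod fed-batch kinetics under a piecewise-constant feed-rate
#' profile and returns an hourly-style sampled batch record. The state is
#' propagated in extensive variables (total biomass X = x*V, total substrate
#' S = s*V, volume V), for which the mass balance
#' dX/dt = mu*X, dS/dt = -mu*X/Y_xs + F*s_feed, dV/dt = F
#' is linear in the forcing, so the biomass/substrate balance is conserved
#' by the integrator to machine precision. Integration uses classical
#' fixed-step fourth-order Runge-Kutta with 10 sub-steps per sampling
#' interval; the feed rate is held constant over each interval.
#'
#' @param params A [fedbatch_params()] object.
#' @param feed_profile Numeric vector of feed rates (L/h), one per sampling
#'   interval; the returned series has `length(feed_profile) + 1` samples.
#' @param seed Integer seed for the measurement noise; the same seed yields a
#'   bitwise-identical batch.
#' @param batch_id Label stored on the batch.
#'
#' @return A `ts_batch` object: list with numeric vectors `t` (h), `u`
#'   (feed rate applied at each sample time and held over the following
#'   interval, L/h; the final entry is `NA` since no interval follows the
#'   last sample), `y` (measured biomass concentration, g/L), plus `batch_id`.
#' @export
simulate_fedbatch <- function(params, feed_profile, seed = 1L,
                              batch_id = "batch") {
  stopifnot(inherits(params, "fedbatch_params"))
  if (length(feed_profile) < 1L || any(!is.finite(feed_profile)) ||
      any(feed_profile < 0))
    stop("'feed_profile' must be a non-empty vector of finite feed rates >= 0")
  n_int <- length(feed_profile)
  X <- params$x0 * params$V0
  S <- params$s0 * params$V0
  V <- params$V0
  x_out <- numeric(n_int + 1L)
  x_out[1L] <- params$x0
  mu_fun <- function(s) params$mu_max * max(s, 0) / (params$K_s + max(s, 0))
  deriv <- function(st, F_in) {
    s <- st[2L] / st[3L]
    mu <- mu_fun(s)
    c(mu * st[1L],
      -mu * st[1L] / params$Y_xs + F_in * params$s_feed,
      F_in)
  }
  n_sub <- 10L
  h <- params$dt / n_sub
  st <- c(X, S, V)
  for (k in seq_len(n_int)) {
    F_in <- feed_profile[k]
    for (j in seq_len(n_sub)) {
      k1 <- deriv(st, F_in)
      k2 <- deriv(st + h / 2 * k1, F_in)
      k3 <- deriv(st + h / 2 * k2, F_in)
      k4 <- deriv(st + h * k3, F_in)
      st <- st + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(!is.finite(st)))
        stop(sprintf(
          "integration failure: non-finite state at interval %d, sub-step %d",
          k, j))
    }
    x_out[k + 1L] <- st[1L] / st[3L]
  }
  y <- x_out
  if (params$noise_sd > 0) {
    set.seed(as.integer(seed))
    y <- y + stats::rnorm(length(y), 0, params$noise_sd)
  }
  ts_batch(t = params$dt * (0:n_int),
           u = c(feed_profile, NA_real_),
           y = y, batch_id = batch_id)
}

#' Construct a time-series batch record
#'
#' @param t Strictly increasing numeric timestamps.
#' @param u Feed rates aligned with `t` (`u[k]` is the feed applied at
#'   `t[k]` and held over the following interval; the last entry may be
#'   `NA`).
#' @param y Measured bacteria concentrations (g/L), finite.
#' @param batch_id Label.
#' @return A `ts_batch` object.
#' @export
ts_batch <- function(t, u, y, batch_id = "batch") {
  if (length(t) < 2L || length(u) != length(t) || length(y) != length(t))
    stop("'t', 'u', 'y' must have equal lengths >= 2")
  if (any(diff(t) <= 0)) stop("'t' must be strictly increasing")
  if (any(!is.finite(y))) stop("'y' must be finite")
  structure(list(t = as.numeric(t), u = as.numeric(u), y = as.numeric(y),
                 batch_id = as.character(batch_id)),
            class = "ts_batch")
}

#' @export
print.ts_batch <- function(x, ...) {
  cat(sprintf("<ts_batch '%s': %d samples, t in [%g, %g], y in [%g, %g] g/L>\n",
              x$batch_id, length(x$t), min(x$t), max(x$t),
              min(x$y), max(x$y)))
  invisible(x)
}

#' The identified linear plant used in the control experiments
#'
#' First-order discrete model of bacteria concentration as a function of
#' substrate feed rate, in shift-operator form
#' `(1 + a1 z^-1) y(k) = (b0 + b1 z^-1) u(k)` with `b0 = 0.673`,
#' `b1 = 0.109` and A-polynomial coefficient `a1 = -0.435`, i.e. the
#' one-step recursion `y(k) = 0.673 u(k) + 0.109 u(k-1) + 0.435 y(k-1)`.
#' Feed-rate amplitude bounds are 10 <= u <= 55 and increment bounds
#' |du| <= 10; the steady-state gain (b0 + b1)/(1 + a1) = 1.384 places both
#' working setpoints (20 and 35 g/L) inside the reachable band
#' [13.8, 76.1] g/L of the feed-rate constraints. Serves as a deterministic
#' reference plant for controller tests.
#'
#' @return A `printed_plant` object with fields `b0`, `b1`, `a1` (the
#'   A-polynomial coefficient, negative here), `u_min`, `u_max`, `du_max`.
#' @export
printed_plant <- function() {
  structure(list(b0 = 0.673, b1 = 0.109, a1 = -0.435,
                 u_min = 10, u_max = 55, du_max = 10),
            class = "printed_plant")
}

#' Advance the reference linear plant one step
#'
#' @param plant A [printed_plant()] object.
#' @param u_now Current feed rate.
#' @param u_prev Previous feed rate.
#' @param y_prev Previous output (g/L).
#' @return The next output `b0*u_now + b1*u_prev - a1*y_prev` (`a1` is the
#'   A-polynomial coefficient, so the recursion adds `0.435 * y_prev`).
#' @export
step_printed_plant <- function(plant, u_now, u_prev, y_prev) {
  stopifnot(inherits(plant, "printed_plant"))
  if (!all(is.finite(c(u_now, u_prev, y_prev))))
    stop("inputs to step_printed_plant must be finite")
  plant$b0 * u_now + plant$b1 * u_prev - plant$a1 * y_prev
}

#' Convert the reference linear plant to ARX form
#'
#' @param plant A [printed_plant()] object.
#' @return An [arx_model()] with `a = a1`, `b = c(b0, b1)`, zero offset and
#'   zero dead time (the plant's `u(k)` term is undelayed).
#' @export
as_arx <- function(plant) {
  stopifnot(inherits(plant, "printed_plant"))
  arx_model(a = plant$a1, b = c(plant$b0, plant$b1), offset = 0,
            dead_time = 0L)
}

#' Build a lagged regression training set from a batch
#'
#' Each row pairs the regressor
#' `[u(t-1), ..., u(t-m), y(t-1), ..., y(t-n)]` (input lags first, then
#' output lags) with the target `y(t)`; rows are formed for every `t` with a
#' complete lag window, giving `length - max(m, n)` rows per batch. Windows
#' never span batch boundaries: build per batch and combine with
#' [bind_training_sets()].
#'
#' @param batch A `ts_batch` (or a list of them, combined per-batch).
#' @param m Number of input (feed-rate) lags, >= 1.
#' @param n Number of output (concentration) lags, >= 1.
#' @return A `training_set`: list with matrix `X` (rows are regressors),
#'   vector `y`, counts `N`, `m`, `n`.
#' @export
make_training_set <- function(batch, m, n) {
  if (is.list(batch) && !inherits(batch, "ts_batch"))
    return(bind_training_sets(lapply(batch, make_training_set, m = m, n = n)))
  stopifnot(inherits(batch, "ts_batch"))
  m <- as.integer(m); n <- as.integer(n)
  if (m < 1L || n < 1L) stop("'m' and 'n' must be >= 1")
  len <- length(batch$y)
  p <- max(m, n)
  if (len <= p)
    stop(sprintf("batch '%s' has %d samples; need at least %d for m=%d, n=%d",
                 batch$batch_id, len, p + 1L, m, n))
  idx <- (p + 1L):len
  X <- matrix(NA_real_, nrow = length(idx), ncol = m + n)
  for (j in seq_len(m)) X[, j] <- batch$u[idx - j]
  for (j in seq_len(n)) X[, m + j] <- batch$y[idx - j]
  colnames(X) <- c(paste0("u_lag", seq_len(m)), paste0("y_lag", seq_len(n)))
  if (any(!is.finite(X)))
    stop("regressors contain non-finite values (feed rate missing for early lags?)")
  structure(list(X = X, y = batch$y[idx], N = length(idx), m = m, n = n),
            class = "training_set")
}

#' Combine training sets row-wise
#'
#' @param sets A list of `training_set` objects with identical lag structure.
#' @return A single combined `training_set`.
#' @export
bind_training_sets <- function(sets) {
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1), "training_set")))
  m <- sets[[1L]]$m; n <- sets[[1L]]$n
  if (!all(vapply(sets, function(s) s$m == m && s$n == n, logical(1))))
    stop("all training sets must share the same lag structure")
  X <- do.call(rbind, lapply(sets, `[[`, "X"))
  y <- unlist(lapply(sets, `[[`, "y"), use.names = FALSE)
  structure(list(X = X, y = y, N = length(y), m = m, n = n),
            class = "training_set")
}

#' Write / read a batch as CSV
#'
#' Plain-text exchange format: header `t,u,y`, one row per sample.
#'
#' @param batch A `ts_batch`.
#' @param path File path.
#' @return `write_batch_csv` returns `path` invisibly; `read_batch_csv`
#'   returns a `ts_batch` (the id is taken from the file name).
#' @export
write_batch_csv <- function(batch, path) {
  stopifnot(inherits(batch, "ts_batch"))
  utils::write.csv(data.frame(t = batch$t, u = batch$u, y = batch$y),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_batch_csv
#' @export
read_batch_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t", "u", "y") %in% names(df)))
    stop("batch CSV must have columns t,u,y")
  ts_batch(df$t, df$u, df$y,
           batch_id = sub("\\.csv$", "", basename(path)))
}
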