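#' Generalized predictive controller settings
#'
#' @param P Prediction horizon (steps).
#' @param L Control horizon (steps), 1 <= L <= P.
#' @param lam Control-increment weight lambda >= 0 in the quadratic cost.
#' @param beta Reference-trajectory smoothing factor in [0, 1); 0 jumps
#'   straight to the setpoint.
#' @param N1,N2 First and last rows of the prediction window used in the
#'   optimization (defaults: the whole horizon).
#' @param u_min,u_max Feed-rate amplitude bounds.
#' @param du_max Feed-rate increment bound (|du| <= du_max).
#' @return A `gpc_config` object.
#' @export
gpc_config <- function(P = 5L, L = 3L, lam = 0.1, beta = 0.7,
                       N1 = 1L, N2 = P, u_min = -Inf, u_max = Inf,
                       du_max = Inf) {
  P <- as.integer(P); L <- as.integer(L)
  N1 <- as.integer(N1); N2 <- as.integer(N2)
  stopifnot(P >= 1L, L >= 1L, L <= P, N1 >= 1L, N1 <= N2, N2 <= P,
            lam >= 0, beta >= 0, beta < 1, du_max > 0, u_min < u_max)
  structure(list(P = P, L = L, lam = lam, beta = beta, N1 = N1, N2 = N2,
                 u_min = u_min, u_max = u_max, du_max = du_max),
            class = "gpc_config")
}

#' Controller state: signal histories and active setpoint
#'
#' @param u_hist Past applied inputs, most recent last (`u(t-1)` at the end).
#' @param y_hist Past measured outputs, most recent last (`y(t-1)` at the
#'   end, the anchor of the free response and reference trajectory).
#' @param y_s Active setpoint (g/L).
#' @return A `controller_state` object.
#' @export
controller_state <- function(u_hist, y_hist, y_s) {
  stopifnot(length(u_hist) >= 1L, length(y_hist) >= 1L,
            all(is.finite(u_hist)), all(is.finite(y_hist)),
            is.finite(y_s))
  structure(list(u_hist = as.numeric(u_hist), y_hist = as.numeric(y_hist),
                 y_s = y_s),
            class = "controller_state")
}

#' Unit step-response coefficients of an ARX model
#'
#' `g[j]` (j = 0, ..., P-1, returned 1-indexed) is the model output at time
#' `j + 1` in response to a unit step in the input starting at time 1, from
#' zero initial conditions with the constant offset ignored (the differencing
#' in the CARIMA predictor cancels constants). Computed by direct simulation
#' of the recursion. With zero dead time `g[1] = b[1]`; with dead time 1 the
#' first coefficient is 0.
#'
#' @param arx An [arx_model()].
#' @param P Number of coefficients.
#' @return Numeric vector of length `P`.
#' @export
step_coefficients <- function(arx, P) {
  stopifnot(inherits(arx, "arx_model"), P >= 1L)
  pad <- length(arx$b) + arx$dead_time + 2L
  arx_forecast(arx,
               u_hist = rep(0, pad), y_hist = rep(0, length(arx$a)),
               u_future = rep(1, P), steps = P, include_offset = FALSE)
}

#' Free response of the model over the prediction horizon
#'
#' Forecast of the next `P` outputs obtained by iterating the ARX model
#' (offset included) from the measured histories with the input frozen at the
#' last applied value, i.e. all future control increments zero. The first
#' predicted output is the one first affected (for zero dead time) by the
#' increment currently being chosen.
#'
#' @param arx An [arx_model()].
#' @param state A [controller_state()].
#' @param P Prediction horizon.
#' @return Numeric vector `F` of length `P`.
#' @export
free_response <- function(arx, state, P) {
  stopifnot(inherits(arx, "arx_model"), inherits(state, "controller_state"))
  n <- length(arx$a)
  need_u <- length(arx$b) + max(arx$dead_time - 1L, 0L)
  if (length(state$y_hist) < n)
    stop(sprintf("free_response needs %d past outputs, have %d",
                 n, length(state$y_hist)))
  if (length(state$u_hist) < need_u)
    stop(sprintf("free_response needs %d past inputs, have %d",
                 need_u, length(state$u_hist)))
  u_last <- state$u_hist[length(state$u_hist)]
  arx_forecast(arx, state$u_hist, state$y_hist,
               u_future = rep(u_last, P), steps = P, include_offset = TRUE)
}

#' Prediction matrices for the GPC control law
#'
#' Builds the lower-triangular Toeplitz step-coefficient matrix `G`
#' (`G[i, j] = g[i - j]`, zero above the diagonal), the free response `F`,
#' and the gain row `dT`: the first row of `(G'G + lambda I)^-1 G'` computed
#' on the rows `N1:N2` of the prediction window.
#'
#' @param arx An [arx_model()].
#' @param state A [controller_state()].
#' @param cfg A [gpc_config()].
#' @return A `prediction_matrices` list with `G` (P x L), `F` (length P),
#'   `dT` (length N2 - N1 + 1), and the window `N1:N2`.
#' @export
prediction_matrices <- function(arx, state, cfg) {
  stopifnot(inherits(cfg, "gpc_config"))
  g <- step_coefficients(arx, cfg$P)
  G <- matrix(0, nrow = cfg$P, ncol = cfg$L)
  for (j in seq_len(cfg$L)) {
    rows <- j:cfg$P
    G[rows, j] <- g[seq_along(rows)]
  }
  Fv <- free_response(arx, state, cfg$P)
  win <- cfg$N1:cfg$N2
  Gm <- G[win, , drop = FALSE]
  H <- crossprod(Gm) + cfg$lam * diag(cfg$L)
  sol <- tryCatch(solve(H, t(Gm)), error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol))) {
    if (cfg$lam == 0)
      stop("G'G is singular with lambda = 0; set lam > 0 to regularize the control law")
    stop("failed to invert G'G + lambda*I")
  }
  structure(list(G = G, F = Fv, dT = sol[1L, ], window = win),
            class = "prediction_matrices")
}

#' Reference trajectory toward the setpoint
#'
#' First-order filtered path anchored at the current measured output
#' `w(t) = y(t)`, then `w(t+j) = beta * w(t+j-1) + (1 - beta) * y_s`.
#' Returns `[w(t+1), ..., w(t+P)]`, a monotone convex-combination path that
#' never overshoots the setpoint.
#'
#' @param state A [controller_state()] (the anchor is the last entry of
#'   `y_hist`; the setpoint is `y_s`).
#' @param cfg A [gpc_config()].
#' @return Numeric vector of length `P`.
#' @export
reference_trajectory <- function(state, cfg) {
  stopifnot(inherits(state, "controller_state"), inherits(cfg, "gpc_config"))
  w <- numeric(cfg$P)
  prev <- state$y_hist[length(state$y_hist)]
  for (j in seq_len(cfg$P)) {
    prev <- cfg$beta * prev + (1 - cfg$beta) * state$y_s
    w[j] <- prev
  }
  w
}

#' Receding-horizon control move
#'
#' Closed-form unconstrained GPC increment `du = dT (W - F)` over the
#' optimization window, then clamped to `[-du_max, du_max]`; the applied
#' input `u = u(t-1) + du` is clamped to `[u_min, u_max]` and the increment
#' recomputed as the realized difference.
#'
#' @param pm A [prediction_matrices()] object.
#' @param W Reference trajectory (length P).
#' @param cfg A [gpc_config()].
#' @param state A [controller_state()] (supplies `u(t-1)`).
#' @return List with `u` (input to apply), `du` (realized increment), and
#'   `du_unconstrained`.
#' @export
control_increment <- function(pm, W, cfg, state) {
  stopifnot(inherits(pm, "prediction_matrices"), length(W) == length(pm$F))
  du_unc <- sum(pm$dT * (W[pm$window] - pm$F[pm$window]))
  du <- min(max(du_unc, -cfg$du_max), cfg$du_max)
  u_prev <- state$u_hist[length(state$u_hist)]
  u <- min(max(u_prev + du, cfg$u_min), cfg$u_max)
  list(u = u, du = u - u_prev, du_unconstrained = du_unc)
}

#' Quadratic GPC cost of a candidate increment sequence
#'
#' `J(U) = (Y - W)'(Y - W) + lambda U'U` with `Y = G U + F`. Provided as the
#' optimization-oracle counterpart of the closed-form control law.
#'
#' @param U Increment sequence (length L).
#' @param pm A [prediction_matrices()] object.
#' @param W Reference trajectory (length P).
#' @param lam Control weight.
#' @return Scalar cost >= 0.
#' @export
cost_J <- function(U, pm, W, lam) {
  stopifnot(length(U) == ncol(pm$G), length(W) == length(pm$F))
  win <- pm$window
  e <- (pm$G %*% U + pm$F - W)[win]
  sum(e^2) + lam * sum(U^2)
}
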