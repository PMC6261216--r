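#' Run a closed-loop GPC tracking experiment
#'
#' At each step the controller (re)builds its prediction matrices from the
#' current ARX model, filters the setpoint into a reference trajectory,
#' computes the clamped control increment, applies the input to the plant and
#' records every signal. Three plant modes are supported:
#' \describe{
#'   \item{`printed_plant`}{the fixed reference linear plant serves as both
#'     plant and controller model (no re-linearization).}
#'   \item{`lssvm`}{the fitted nonlinear model itself is simulated as the
#'     plant (NARX recursion) and re-linearized every
#'     `relinearize_every` steps for the controller.}
#'   \item{`list(params = fedbatch_params(), feed_scale = ...)`}{the Monod
#'     fed-batch simulator is the plant (controller input times `feed_scale`
#'     = feed rate in L/h); requires a fitted `model` for the controller.}
#' }
#'
#' @param plant Plant specification (see above).
#' @param gpc A [gpc_config()]; its `u_min`/`u_max`/`du_max` constrain the
#'   applied input.
#' @param setpoints Data frame with columns `start_step`, `value` (g/L),
#'   ordered, first `start_step` = 1.
#' @param steps Number of control steps.
#' @param init List with `u0` (initial input), `du0` (increment that
#'   produced it, used to back-fill the input history), `y0` (initial
#'   measured output).
#' @param model Optional `lssvm` model for the controller (required for the
#'   fed-batch plant; defaults to the plant itself otherwise).
#' @param relinearize_every Steps between Taylor re-linearizations of an
#'   LS-SVM controller model (1 = every sampling instant).
#' @param seed Integer seed (used only when the plant adds measurement
#'   noise).
#' @return Data frame log with columns `k`, `u`, `du`, `y`, `w` (first
#'   reference-trajectory value), `setpoint`.
#' @export
run_closed_loop <- function(plant, gpc, setpoints, steps = 360L,
                            init = list(u0 = 15, du0 = 4.5, y0 = 14.5),
                            model = NULL, relinearize_every = 1L,
                            seed = 1L) {
  stopifnot(inherits(gpc, "gpc_config"), steps >= 1L,
            is.data.frame(setpoints),
            all(c("start_step", "value") %in% names(setpoints)))
  setpoints <- setpoints[order(setpoints$start_step), , drop = FALSE]
  if (setpoints$start_step[1L] != 1L)
    stop("the setpoint schedule must start at step 1")
  if (anyDuplicated(setpoints$start_step))
    stop("setpoint schedule has overlapping segments")
  sp_at <- function(k) setpoints$value[max(which(setpoints$start_step <= k))]

  # --- resolve plant and controller model -------------------------------
  mode <- if (inherits(plant, "printed_plant")) "printed"
          else if (inherits(plant, "lssvm")) "model"
          else if (is.list(plant) && inherits(plant$params, "fedbatch_params"))
            "fedbatch"
          else stop("unrecognized plant specification")
  if (mode == "printed") {
    arx <- as_arx(plant)
    lin_model <- NULL
  } else if (mode == "model") {
    plant_model <- plant
    lin_model <- if (is.null(model)) plant else model
    arx <- NULL
  } else {
    if (is.null(model) || !inherits(model, "lssvm"))
      stop("the fed-batch plant mode requires a fitted 'lssvm' controller model")
    lin_model <- model
    arx <- NULL
    feed_scale <- if (is.null(plant$feed_scale)) 1 else plant$feed_scale
    fb <- plant$params
    fb_state <- c(fb$x0 * fb$V0, fb$s0 * fb$V0, fb$V0)  # (X, S, V)
    if (fb$noise_sd > 0) set.seed(as.integer(seed))
  }
  m_lag <- if (!is.null(lin_model)) lin_model$m else 1L
  n_lag <- if (!is.null(lin_model)) lin_model$n else 1L

  # --- histories --------------------------------------------------------
  hist_u_len <- max(m_lag, 2L) + 2L
  hist_y_len <- max(n_lag, 1L) + 1L
  u_hist <- c(rep(init$u0 - init$du0, hist_u_len - 1L), init$u0)
  y_hist <- rep(init$y0, hist_y_len)

  log <- data.frame(k = seq_len(steps), u = NA_real_, du = NA_real_,
                    y = NA_real_, w = NA_real_, setpoint = NA_real_)
  for (k in seq_len(steps)) {
    sp <- sp_at(k)
    if (!is.null(lin_model) &&
        ((k - 1L) %% relinearize_every == 0L || is.null(arx))) {
      lu <- length(u_hist); ly <- length(y_hist)
      x0 <- c(u_hist[lu - seq_len(m_lag) + 1L],
              y_hist[ly - seq_len(n_lag) + 1L])
      arx <- linearize_at(lin_model, x0)
    }
    state <- controller_state(u_hist, y_hist, sp)
    pm <- tryCatch(prediction_matrices(arx, state, gpc),
                   error = function(e)
                     stop(sprintf("step %d: %s", k, conditionMessage(e))))
    W <- reference_trajectory(state, gpc)
    mv <- control_increment(pm, W, gpc, state)

    y_new <- switch(mode,
      printed = step_printed_plant(plant, mv$u,
                                   u_hist[length(u_hist)],
                                   y_hist[length(y_hist)]),
      model = {
        # NARX with unit dead time: the input applied now first affects the
        # next measurement, so the current output uses pre-update histories
        lu <- length(u_hist); ly <- length(y_hist)
        x_now <- c(u_hist[lu - seq_len(m_lag) + 1L],
                   y_hist[ly - seq_len(n_lag) + 1L])
        predict(plant_model, x_now)
      },
      fedbatch = {
        st <- fedbatch_substep(fb, fb_state, mv$u * feed_scale)
        if (any(!is.finite(st)))
          stop(sprintf("step %d: fed-batch integration produced non-finite state", k))
        fb_state <- st
        y_k <- st[1L] / st[3L]
        if (fb$noise_sd > 0) y_k <- y_k + stats::rnorm(1L, 0, fb$noise_sd)
        y_k
      })

    u_hist <- c(u_hist[-1L], mv$u)
    y_hist <- c(y_hist[-1L], y_new)
    log$u[k] <- mv$u; log$du[k] <- mv$du; log$y[k] <- y_new
    log$w[k] <- W[1L]; log$setpoint[k] <- sp
  }
  attr(log, "gpc") <- gpc
  attr(log, "setpoints") <- setpoints
  log
}

# One control interval of the fed-batch plant in extensive state (X, S, V),
# RK4 with 10 sub-steps, constant feed F (L/h).
fedbatch_substep <- function(fb, st, F_in) {
  mu_fun <- function(s) fb$mu_max * max(s, 0) / (fb$K_s + max(s, 0))
  deriv <- function(z) {
    s <- z[2L] / z[3L]
    mu <- mu_fun(s)
    c(mu * z[1L], -mu * z[1L] / fb$Y_xs + F_in * fb$s_feed, F_in)
  }
  h <- fb$dt / 10
  for (j in 1:10) {
    k1 <- deriv(st); k2 <- deriv(st + h / 2 * k1)
    k3 <- deriv(st + h / 2 * k2); k4 <- deriv(st + h * k3)
    st <- st + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  st
}

#' Summarize setpoint-tracking quality of a closed-loop log
#'
#' Per setpoint segment: `max_abs_error_steady` is the worst |y - setpoint|
#' over the final third of the segment; `max_abs_error_settled` the worst
#' deviation from the first time the output crosses (or touches) the
#' setpoint onward; `settling_step` the first step with |y - setpoint|
#' within 2% of the setpoint. A monotone approach that never crosses the
#' setpoint has no crossing instant, in which case the settled window starts
#' at the settling step instead (`NA` if the band is never entered either). Constraint violations
#' count log rows whose input or increment exceeds the configured bounds
#' (beyond a 1e-9 tolerance).
#'
#' @param log A closed-loop log from [run_closed_loop()].
#' @param gpc Optional [gpc_config()] supplying the bounds (defaults to the
#'   one recorded on the log).
#' @return A `tracking_report`: list with a per-segment data frame and the
#'   overall maxima.
#' @export
evaluate_tracking <- function(log, gpc = attr(log, "gpc")) {
  stopifnot(is.data.frame(log), nrow(log) >= 1L)
  sp <- attr(log, "setpoints")
  if (is.null(sp))
    sp <- data.frame(start_step = 1L, value = log$setpoint[1L])
  starts <- sp$start_step
  ends <- c(starts[-1L] - 1L, nrow(log))
  seg <- data.frame(start_step = starts, end_step = ends,
                    setpoint = sp$value,
                    max_abs_error_steady = NA_real_,
                    max_abs_error_settled = NA_real_,
                    settling_step = NA_integer_)
  for (i in seq_along(starts)) {
    rows <- starts[i]:ends[i]
    err <- log$y[rows] - sp$value[i]
    n_seg <- length(rows)
    tail_rows <- rows[(n_seg - floor(n_seg / 3) + 1L):n_seg]
    seg$max_abs_error_steady[i] <- max(abs(log$y[tail_rows] - sp$value[i]))
    s0 <- if (starts[i] > 1L) sign(log$y[starts[i] - 1L] - sp$value[i])
          else sign(err[1L])
    cross <- which(err == 0 | sign(err) != s0)
    inband <- which(abs(err) <= 0.02 * abs(sp$value[i]))
    if (length(inband) > 0L)
      seg$settling_step[i] <- rows[inband[1L]]
    settled_from <- if (length(cross) > 0L) cross[1L]
                    else if (length(inband) > 0L) inband[1L]
                    else NA_integer_
    if (!is.na(settled_from))
      seg$max_abs_error_settled[i] <- max(abs(err[settled_from:n_seg]))
  }
  viol <- 0L
  if (!is.null(gpc)) {
    tol <- 1e-9
    viol <- sum(log$u > gpc$u_max + tol | log$u < gpc$u_min - tol |
                  abs(log$du) > gpc$du_max + tol)
  }
  structure(list(segments = seg,
                 max_abs_error_steady = max(seg$max_abs_error_steady),
                 max_abs_error_settled =
                   if (all(is.na(seg$max_abs_error_settled))) NA_real_
                   else max(seg$max_abs_error_settled, na.rm = TRUE),
                 constraint_violations = viol),
            class = "tracking_report")
}

#' @export
print.tracking_report <- function(x, ...) {
  cat("<tracking_report>\n")
  print(x$segments)
  cat(sprintf("overall: steady %.4g, settled %.4g, violations %d\n",
              x$max_abs_error_steady, x$max_abs_error_settled,
              x$constraint_violations))
  invisible(x)
}

#' Identification study on synthetic fed-batch data
#'
#' Generates `n_batches` fed-batch fermentations under randomized
#' piecewise-constant feed profiles, uses all but the last two batches to
#' train, the second-to-last as the PSO calibration set, and the last as the
#' held-out test batch. A PSO-tuned LS-SVM (with the untuned default
#' hyperparameters seeded into the initial swarm) is compared against the
#' untuned default fit, both refit on all training + calibration batches and
#' scored one-step-ahead on the test batch.
#'
#' @param n_batches Number of batches (>= 3).
#' @param params A [fedbatch_params()] object.
#' @param batch_hours Duration of each batch (h); hourly samples.
#' @param m,n Input/output lag counts of the NARX regressor.
#' @param pso A [pso_config()] (its `seed` is overridden by `seed`).
#' @param default_hyper Untuned baseline hyperparameters.
#' @param seed Master seed for feed profiles, noise and the swarm.
#' @return A report list with tuned/default hyperparameters and test
#'   RMSE/MAXE/MAPE, plus `tuned_no_worse`.
#' @export
run_identification_study <- function(n_batches = 10L,
                                     params = fedbatch_params(),
                                     batch_hours = 24L,
                                     m = 2L, n = 2L,
                                     pso = pso_config(),
                                     default_hyper = kernel_hyperparams(1, 1),
                                     seed = 1L) {
  stopifnot(n_batches >= 3L)
  seed <- as.integer(seed)
  set.seed(seed)
  batches <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    # feed held constant over 4-h blocks, drawn uniformly; ramps the reactor
    # through a broad operating range
    n_blocks <- ceiling(batch_hours / 4)
    levels <- stats::runif(n_blocks, 0.1, 1.2)
    profile <- rep(levels, each = 4L)[seq_len(batch_hours)]
    batches[[b]] <- simulate_fedbatch(params, profile,
                                      seed = seed + 1000L + b,
                                      batch_id = sprintf("batch_%02d", b))
  }
  train_idx <- seq_len(n_batches - 2L)
  calib_idx <- n_batches - 1L
  test_idx <- n_batches
  train <- make_training_set(batches[train_idx], m = m, n = n)
  calib <- make_training_set(batches[[calib_idx]], m = m, n = n)
  test <- make_training_set(batches[[test_idx]], m = m, n = n)

  pso$seed <- seed
  tuned <- optimize_hyperparams(train, calib, pso,
                                init_guesses =
                                  rbind(c(default_hyper$C,
                                          default_hyper$sigma)))
  full_train <- bind_training_sets(list(train, calib))
  model_tuned <- fit_lssvm(full_train, tuned$hyper)
  model_default <- fit_lssvm(full_train, default_hyper)
  met_tuned <- rmse_maxe(test$y, predict(model_tuned, test$X))
  met_default <- rmse_maxe(test$y, predict(model_default, test$X))
  report <- list(
    n_batches = n_batches,
    lag_spec = c(m = m, n = n),
    tuned_hyper = list(C = tuned$hyper$C, sigma = tuned$hyper$sigma),
    default_hyper = list(C = default_hyper$C, sigma = default_hyper$sigma),
    calib_fitness = tuned$fitness,
    tuned = list(rmse = met_tuned$rmse, maxe = met_tuned$maxe,
                 mape = mape(test$y, predict(model_tuned, test$X))),
    default = list(rmse = met_default$rmse, maxe = met_default$maxe,
                   mape = mape(test$y, predict(model_default, test$X))),
    y_test_range = diff(range(test$y)),
    tuned_no_worse = met_tuned$rmse <= met_default$rmse)
  if (!report$tuned_no_worse)
    warning("PSO-tuned model scored worse than the untuned default on the test batch")
  report
}
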