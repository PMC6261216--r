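# direct simulation of an ARX model under a given future-input path,
# used as the oracle for step coefficients, free response and superposition
sim_arx_path <- function(arx, u_hist, y_hist, u_path) {
  fermgpc:::arx_forecast(arx, u_hist, y_hist, u_path, length(u_path))
}

test_that("step coefficients equal a brute-force unit-step simulation", {
  arx <- as_arx(printed_plant())   # a = -0.435, b = (0.673, 0.109), d = 0
  P <- 6
  g <- step_coefficients(arx, P)
  # oracle: simulate the recursion under u = 1 from rest, offset ignored
  y <- numeric(P); u <- rep(1, P)
  for (k in 1:P) {
    y_prev <- if (k == 1) 0 else y[k - 1]
    u_prev <- if (k == 1) 0 else u[k - 1]
    y[k] <- 0.673 * u[k] + 0.109 * u_prev + 0.435 * y_prev
  }
  expect_equal(g, y, tolerance = 1e-12)
  expect_equal(g[1], 0.673)
  expect_equal(g[2], 0.673 + 0.109 + 0.435 * 0.673)
})

test_that("a pure-gain model has a flat step response", {
  arx <- arx_model(a = 0, b = 2.5, offset = 0, dead_time = 1)
  expect_equal(step_coefficients(arx, 4), c(0, 2.5, 2.5, 2.5))
})

test_that("first-sample causality follows the dead time", {
  b <- c(0.8, 0.2)
  g0 <- step_coefficients(arx_model(a = 0.1, b = b, dead_time = 0), 3)
  g1 <- step_coefficients(arx_model(a = 0.1, b = b, dead_time = 1), 3)
  expect_equal(g0[1], 0.8)
  expect_equal(g1[1], 0)
  expect_equal(g1[2], 0.8)
})

test_that("the free response is the frozen-input forecast", {
  arx <- arx_model(a = c(-0.5), b = c(0.4, 0.1), offset = 1, dead_time = 1)
  # equilibrium: constant histories at the fixed point of the frozen input
  u_eq <- 6
  y_eq <- (sum(arx$b) * u_eq + arx$offset) / (1 + sum(arx$a))
  st <- controller_state(u_hist = rep(u_eq, 4), y_hist = rep(y_eq, 3),
                         y_s = 10)
  expect_equal(free_response(arx, st, 5), rep(y_eq, 5), tolerance = 1e-10)
  # P = 1 reduces to the one-step prediction
  st2 <- simple_state()
  f1 <- free_response(arx, st2, 1)
  u_last <- st2$u_hist[length(st2$u_hist)]
  expect_equal(f1, fermgpc:::arx_step(arx, st2$u_hist, st2$y_hist))
  expect_error(free_response(arx, controller_state(1, 1, 1), 3), "past")
})

test_that("GU + F reproduces direct simulation for random increment sequences", {
  for (seed in 1:6) {
    arx <- rand_stable_arx(seed, n = 2, m = 1, dead_time = seed %% 2)
    st <- simple_state(seed = seed)
    cfg <- gpc_config(P = 7, L = 3, lam = 0.2, beta = 0.5)
    pm <- prediction_matrices(arx, st, cfg)
    set.seed(seed + 50)
    U <- rnorm(3)
    u_last <- st$u_hist[length(st$u_hist)]
    u_path <- u_last + cumsum(c(U, rep(0, 4)))
    sim <- sim_arx_path(arx, st$u_hist, st$y_hist, u_path)
    expect_equal(as.vector(pm$G %*% U + pm$F), sim, tolerance = 1e-10)
  }
})

test_that("the reference trajectory filters from the current output to the setpoint", {
  st <- controller_state(u_hist = 5, y_hist = c(3, 0), y_s = 20)
  expect_equal(reference_trajectory(st, gpc_config(P = 3, L = 1, beta = 0)),
               c(20, 20, 20))
  expect_equal(reference_trajectory(st, gpc_config(P = 2, L = 1, beta = 0.5)),
               c(10, 15))
  W <- reference_trajectory(st, gpc_config(P = 10, L = 2, beta = 0.8))
  expect_true(all(diff(W) > 0))
  expect_true(all(W <= 20 & W >= 0))
})

test_that("the closed-form increment minimizes the quadratic cost", {
  for (seed in 1:8) {
    arx <- rand_stable_arx(seed + 20, n = 2, m = 1, dead_time = 1L)
    st <- simple_state(y_s = 15, seed = seed)
    lam <- runif(1, 0.01, 2)
    cfg <- gpc_config(P = 6, L = 3, lam = lam, beta = 0.4)
    pm <- prediction_matrices(arx, st, cfg)
    W <- reference_trajectory(st, cfg)
    mv <- control_increment(pm, W, cfg, st)
    # numerical minimization oracle over the full increment sequence
    o <- stats::optim(rep(0, 3), cost_J, pm = pm, W = W, lam = lam,
                      method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 5000))
    expect_equal(mv$du_unconstrained, o$par[1], tolerance = 1e-6)
    # spot-check optimality against random candidates
    set.seed(seed)
    U_star <- qr.solve(rbind(pm$G, sqrt(lam) * diag(3)),
                       c(W - pm$F, rep(0, 3)))
    J_star <- cost_J(U_star, pm, W, lam)
    J_rand <- replicate(200, cost_J(U_star + rnorm(3, 0, 0.5), pm, W, lam))
    expect_true(all(J_rand >= J_star - 1e-12))
  }
})

test_that("the increment vanishes when no correction is predicted or lambda dominates", {
  arx <- as_arx(printed_plant())
  st <- simple_state(y_s = 18)
  cfg <- gpc_config(P = 5, L = 3, lam = 0.1, beta = 0.7)
  pm <- prediction_matrices(arx, st, cfg)
  mv0 <- control_increment(pm, pm$F, cfg, st)   # W = F
  expect_equal(mv0$du, 0, tolerance = 1e-12)
  expect_equal(mv0$u, st$u_hist[length(st$u_hist)])
  cfg_hi <- gpc_config(P = 5, L = 3, lam = 1e12, beta = 0.7)
  pm_hi <- prediction_matrices(arx, st, cfg_hi)
  W <- reference_trajectory(st, cfg_hi)
  expect_lt(abs(control_increment(pm_hi, W, cfg_hi, st)$du), 1e-8)
})

test_that("constraint clamping limits the applied input and realized increment", {
  arx <- as_arx(printed_plant())
  st <- controller_state(u_hist = c(10, 10), y_hist = c(5, 5), y_s = 50)
  cfg <- gpc_config(P = 5, L = 3, lam = 0.1, beta = 0,
                    u_min = 10, u_max = 12, du_max = 1.5)
  pm <- prediction_matrices(arx, st, cfg)
  W <- reference_trajectory(st, cfg)
  mv <- control_increment(pm, W, cfg, st)
  expect_gt(mv$du_unconstrained, 1.5)  # large error demands a big move
  expect_equal(mv$du, 1.5)
  expect_equal(mv$u, 11.5)
})

test_that("cost_J is a nonnegative quadratic with the documented zero", {
  arx <- as_arx(printed_plant())
  st <- simple_state()
  cfg <- gpc_config(P = 4, L = 2, lam = 0.3, beta = 0.5)
  pm <- prediction_matrices(arx, st, cfg)
  expect_equal(cost_J(c(0, 0), pm, pm$F, 0.3), 0)
  set.seed(1)
  for (i in 1:20)
    expect_gte(cost_J(rnorm(2), pm, reference_trajectory(st, cfg), 0.3), 0)
})

test_that("one-step GPC with no weighting inverts the model", {
  arx <- as_arx(printed_plant())   # d = 0 so the current move acts now
  st <- simple_state(y_s = 25)
  cfg <- gpc_config(P = 1, L = 1, lam = 0, beta = 0.3)
  pm <- prediction_matrices(arx, st, cfg)
  W <- reference_trajectory(st, cfg)
  mv <- control_increment(pm, W, cfg, st)
  y_pred <- pm$F[1] + pm$G[1, 1] * mv$du
  expect_equal(y_pred, W[1], tolerance = 1e-10)
})

test_that("a singular normal matrix with zero weighting asks for regularization", {
  arx <- arx_model(a = 0.1, b = c(0.5), dead_time = 1)  # g starts with 0
  st <- simple_state()
  cfg <- gpc_config(P = 1, L = 1, lam = 0, beta = 0.5)
  # with d = 1 and P = 1 the only step coefficient is 0: G'G is singular
  expect_error(prediction_matrices(arx, st, cfg), "lam")
})
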