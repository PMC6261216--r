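# Fixture builders shared across test files. Everything is generated in code
# under explicit seeds; no stored data.

# A training set with random regressors and a smooth target surface.
rand_training_set <- function(N = 10, D = 2, seed = 1,
                              fn = function(X) sin(2 * X[, 1]) +
                                0.5 * X[, 2]^2) {
  set.seed(seed)
  X <- matrix(runif(N * D, 0, 3), ncol = D)
  structure(list(X = X, y = fn(X) , N = N,
                 m = max(D - 1L, 1L), n = 1L),
            class = "training_set")
}

# A fitted LS-SVM on random smooth data (for gradient / linearization tests).
rand_lssvm <- function(seed = 1, N = 15, D = 3, C = 50, sigma = 1.2) {
  tr <- rand_training_set(N, D, seed,
                          fn = function(X) cos(X[, 1]) + X[, 2] * X[, 3])
  tr$m <- D - 1L; tr$n <- 1L
  fit_lssvm(tr, kernel_hyperparams(C, sigma))
}

# A random stable ARX model (spectral radius of A's companion roots < 0.9).
rand_stable_arx <- function(seed = 1, n = 2, m = 1, dead_time = 1L) {
  set.seed(seed)
  repeat {
    a <- runif(n, -0.9, 0.9) / n
    if (all(Mod(polyroot(c(1, a))) > 1.1)) break
  }
  arx_model(a = a, b = runif(m + 1, -1, 1.5), offset = runif(1, -2, 2),
            dead_time = dead_time)
}

# Data generated from a known linear recursion
# y(t) = b0 u(t-1) + a y(t-1) + c, for fit-then-linearize recovery tests.
linear_plant_batch <- function(len = 150, b0 = 0.5, a = 0.3, c = 2,
                               seed = 1, u_range = c(0, 10)) {
  set.seed(seed)
  u <- runif(len, u_range[1], u_range[2])
  y <- numeric(len)
  y[1] <- c / (1 - a)
  for (t in 2:len) y[t] <- b0 * u[t - 1] + a * y[t - 1] + c
  ts_batch(seq_len(len), u, y, batch_id = "linear")
}

# Canonical controller state with enough history for small ARX orders.
simple_state <- function(y_s = 12, seed = 1) {
  set.seed(seed)
  controller_state(u_hist = runif(6, 2, 10), y_hist = runif(6, 5, 20),
                   y_s = y_s)
}
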