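#' Particle swarm optimizer settings
#'
#' Defaults follow common practice for 2-D hyperparameter searches: 20
#' particles, 150 iterations, cognitive factor `c1 = 1.5`, social factor
#' `c2 = 1.7`, search box `C` in (0, 2000] (lower bound raised to 1e-3 since
#' the regularization parameter must be strictly positive) and `sigma` in
#' [0.01, 100]. The inertia weight decays linearly from `inertia[1]` to
#' `inertia[2]` over the run (a single value gives a constant weight).
#' Velocities are capped at `v_max_frac` of the box width per dimension.
#'
#' @param n_particles Swarm size.
#' @param n_iters Number of iterations.
#' @param c1,c2 Cognitive and social acceleration factors, >= 0.
#' @param inertia Inertia weight schedule: length-2 (start, end) for linear
#'   decay, or a single constant.
#' @param bounds_C,bounds_sigma Length-2 search intervals.
#' @param v_max_frac Velocity cap as a fraction of each bound width.
#' @param seed Integer seed; the whole run is reproducible from it.
#' @return A `pso_config` object (with a `bounds` matrix, one row per
#'   dimension).
#' @export
pso_config <- function(n_particles = 20L, n_iters = 150L,
                       c1 = 1.5, c2 = 1.7, inertia = c(0.9, 0.4),
                       bounds_C = c(1e-3, 2000), bounds_sigma = c(0.01, 100),
                       v_max_frac = 0.2, seed = 1L) {
  stopifnot(n_particles >= 1L, n_iters >= 0L, c1 >= 0, c2 >= 0,
            length(bounds_C) == 2L, length(bounds_sigma) == 2L,
            bounds_C[1L] < bounds_C[2L], bounds_sigma[1L] < bounds_sigma[2L],
            bounds_C[1L] > 0, bounds_sigma[1L] > 0,
            v_max_frac > 0, length(inertia) %in% 1:2)
  if (length(inertia) == 1L) inertia <- rep(inertia, 2L)
  bounds <- rbind(C = bounds_C, sigma = bounds_sigma)
  structure(list(n_particles = as.integer(n_particles),
                 n_iters = as.integer(n_iters),
                 c1 = c1, c2 = c2, inertia = inertia,
                 bounds = bounds,
                 v_max = v_max_frac * (bounds[, 2L] - bounds[, 1L]),
                 seed = as.integer(seed)),
            class = "pso_config")
}

#' One particle velocity/position update
#'
#' Applies the standard update
#' `V <- w*V + c1*r1*(pbest - X) + c2*r2*(gbest - X); X <- X + V`
#' with `r1`, `r2` drawn uniformly on [0, 1] per dimension, then clamps the
#' velocity to `[-v_max, v_max]` and the position to the search bounds,
#' zeroing the velocity component of any clamped dimension.
#'
#' @param p A particle: list with `position`, `velocity`, `pbest`,
#'   `pbest_fitness`.
#' @param gbest Global best position.
#' @param cfg A [pso_config()].
#' @param w Inertia weight for this iteration.
#' @param r1,r2 Optional uniform draws (vectors, one per dimension); drawn
#'   from the current RNG stream when omitted.
#' @return The updated particle.
#' @export
update_particle <- function(p, gbest, cfg, w,
                            r1 = stats::runif(length(p$position)),
                            r2 = stats::runif(length(p$position))) {
  v <- w * p$velocity +
    cfg$c1 * r1 * (p$pbest - p$position) +
    cfg$c2 * r2 * (gbest - p$position)
  v <- pmin(pmax(v, -cfg$v_max), cfg$v_max)
  x <- p$position + v
  lo <- cfg$bounds[, 1L]; hi <- cfg$bounds[, 2L]
  clamped <- x < lo | x > hi
  x <- pmin(pmax(x, lo), hi)
  v[clamped] <- 0
  p$position <- x
  p$velocity <- v
  p
}

#' Minimize a fitness function by particle swarm search
#'
#' Positions are initialized uniformly within the bounds and velocities
#' uniformly within `[-v_max, v_max]`; each iteration updates every particle,
#' evaluates its fitness, and refreshes personal and global bests. The global
#' best fitness trace is non-increasing by construction. With `n_iters = 0`
#' the best of the initial swarm is returned.
#'
#' @param fitness Function mapping a position vector (length = number of
#'   rows of `cfg$bounds`) to a scalar to be minimized; a non-finite return
#'   is treated as `+Inf` (the position can never become a best).
#' @param cfg A [pso_config()].
#' @param init_guesses Optional matrix (one row per guess) of positions to
#'   seed into the initial swarm, replacing random initial positions.
#' @return List with `par` (best position), `value` (its fitness), and
#'   `trace` (data frame `iter`, one column per dimension of the running
#'   global best, `gbest_fitness`).
#' @export
pso_optimize <- function(fitness, cfg, init_guesses = NULL) {
  stopifnot(inherits(cfg, "pso_config"), is.function(fitness))
  D <- nrow(cfg$bounds)
  lo <- cfg$bounds[, 1L]; hi <- cfg$bounds[, 2L]
  set.seed(cfg$seed)
  eval_fit <- function(x) {
    f <- tryCatch(fitness(x), error = function(e) Inf)
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) Inf else f
  }
  particles <- lapply(seq_len(cfg$n_particles), function(i) {
    pos <- lo + stats::runif(D) * (hi - lo)
    vel <- stats::runif(D, -cfg$v_max, cfg$v_max)
    list(position = pos, velocity = vel, pbest = pos, pbest_fitness = Inf)
  })
  if (!is.null(init_guesses)) {
    init_guesses <- rbind(init_guesses)
    k <- min(nrow(init_guesses), cfg$n_particles)
    for (i in seq_len(k)) {
      pos <- pmin(pmax(as.numeric(init_guesses[i, ]), lo), hi)
      particles[[i]]$position <- pos
      particles[[i]]$pbest <- pos
    }
  }
  for (i in seq_along(particles)) {
    f <- eval_fit(particles[[i]]$position)
    particles[[i]]$pbest_fitness <- f
    particles[[i]]$pbest <- particles[[i]]$position
  }
  gi <- which.min(vapply(particles, `[[`, numeric(1), "pbest_fitness"))
  gbest <- particles[[gi]]$pbest
  gbest_fitness <- particles[[gi]]$pbest_fitness

  trace <- matrix(NA_real_, nrow = cfg$n_iters + 1L, ncol = D + 2L)
  trace[1L, ] <- c(0, gbest, gbest_fitness)
  if (cfg$n_iters > 0L) {
    w_sched <- if (cfg$n_iters == 1L) cfg$inertia[1L] else
      seq(cfg$inertia[1L], cfg$inertia[2L], length.out = cfg$n_iters)
    for (it in seq_len(cfg$n_iters)) {
      for (i in seq_along(particles)) {
        p <- update_particle(particles[[i]], gbest, cfg, w = w_sched[it])
        f <- eval_fit(p$position)
        if (f < p$pbest_fitness) {
          p$pbest <- p$position
          p$pbest_fitness <- f
        }
        if (f < gbest_fitness) {
          gbest <- p$position
          gbest_fitness <- f
        }
        particles[[i]] <- p
      }
      trace[it + 1L, ] <- c(it, gbest, gbest_fitness)
    }
  }
  trace <- as.data.frame(trace)
  names(trace) <- c("iter", paste0("gbest_", rownames(cfg$bounds)),
                    "gbest_fitness")
  list(par = stats::setNames(gbest, rownames(cfg$bounds)),
       value = gbest_fitness, trace = trace)
}

#' Calibration-set MAPE of an LS-SVM fit, as a PSO fitness
#'
#' Fits an LS-SVM on `train` with the candidate hyperparameters and returns
#' the mean absolute percentage error of its predictions on `calib` (held
#' out, so degenerate interpolating fits do not win). A failed fit returns
#' `+Inf` so the candidate can never be selected.
#'
#' @param hyper A [kernel_hyperparams()] object.
#' @param train,calib `training_set` objects with matching lag structure.
#' @return Scalar fitness (lower is better).
#' @export
pso_fitness <- function(hyper, train, calib) {
  tryCatch({
    model <- suppressWarnings(fit_lssvm(train, hyper))
    mape(calib$y, predict(model, calib$X))
  }, error = function(e) Inf)
}

#' Tune LS-SVM hyperparameters by particle swarm optimization
#'
#' Searches `{C, sigma}` within the configured bounds, minimizing the
#' calibration MAPE ([pso_fitness()]) or, optionally, the training-set MAPE.
#'
#' @param train Training set for model fitting.
#' @param calib Held-out calibration set scored by the fitness (ignored when
#'   `fitness_on = "train"`).
#' @param cfg A [pso_config()].
#' @param fitness_on `"calib"` (default) or `"train"`.
#' @param init_guesses Optional hyperparameter guesses (rows of `(C, sigma)`)
#'   seeded into the initial swarm.
#' @return List with `hyper` (a [kernel_hyperparams()]), `fitness`, `trace`.
#' @export
optimize_hyperparams <- function(train, calib, cfg,
                                 fitness_on = c("calib", "train"),
                                 init_guesses = NULL) {
  stopifnot(inherits(train, "training_set"))
  fitness_on <- match.arg(fitness_on)
  score_set <- if (fitness_on == "calib") {
    stopifnot(inherits(calib, "training_set"))
    calib
  } else train
  if (train$N < 2L || score_set$N < 1L)
    stop("empty or too-small train/calibration set")
  fitness <- function(pos)
    pso_fitness(kernel_hyperparams(pos[1L], pos[2L]), train, score_set)
  res <- pso_optimize(fitness, cfg, init_guesses = init_guesses)
  list(hyper = kernel_hyperparams(res$par[["C"]], res$par[["sigma"]]),
       fitness = res$value, trace = res$trace)
}
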