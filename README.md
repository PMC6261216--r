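# fermgpc

Data-driven modelling and predictive control of bacteria concentration
in fed-batch fermentation.

## The problem

In a fed-batch fermenter the only routinely available handle on biomass
growth is the substrate feed rate `u(t)` (L/h), and the controlled
variable is the bacteria concentration `y(t)` (g/L). First-principles
models of the culture are rarely accurate enough for model-based
control, so this package takes the black-box route:

1. **Identify** a one-step-ahead NARX model of the culture from logged
   batches by least-squares support vector machine (LS-SVM) regression
   with a Gaussian (RBF) kernel,

   `y(t) = f(u(t-1), ..., u(t-m), y(t-1), ..., y(t-n))`,

   where `f` is the kernel expansion
   `f(x) = Σ_i α_i exp(-‖x - x_i‖² / σ²) + δ` obtained from one dense
   linear (KKT) solve — no quadratic programming.
2. **Tune** the two hyperparameters — regularization constant `C` and
   kernel width `σ` — by particle swarm optimization (PSO), scoring
   each candidate by its mean absolute percentage error on a held-out
   calibration batch.
3. **Linearize** the fitted model at the current operating point by a
   first-order Taylor expansion (analytic gradient), giving a local ARX
   model `A(z⁻¹) y(t) = B(z⁻¹) u(t-1) + c`.
4. **Control** with a generalized predictive controller (GPC) on the
   CARIMA increment form: minimize
   `J = Σ_{j=N1}^{N2} (ŷ(t+j) − w(t+j))² + λ Σ_{j=1}^{L} Δu(t+j−1)²`
   over a control horizon `L` and prediction horizon `P`, apply the
   first increment, and clamp it to the feed-rate amplitude and
   rate constraints.

A Monod-kinetics fed-batch simulator (exact mass balance, fixed-step
RK4, seeded measurement noise) generates training batches, and a
closed-loop orchestrator ties model, linearizer, controller and plant
together, with re-linearization at a configurable cadence.

## Worked example

Simulate four batches, tune and fit a model, linearize it, and run the
controller on the built-in linear reference plant:

```r
library(fermgpc)
set.seed(42)

# --- data: 24 h batches under randomized piecewise-constant feeding
params <- fedbatch_params()          # Monod defaults, dt = 1 h
profiles <- replicate(4, rep(runif(6, 0.1, 1.2), each = 4), simplify = FALSE)
batches <- lapply(1:4, function(b)
  simulate_fedbatch(params, profiles[[b]], seed = 100 + b,
                    batch_id = sprintf("batch_%02d", b)))

# --- identification: train on 3 batches, calibrate PSO on the 4th
train <- make_training_set(batches[1:3], m = 2, n = 2)
calib <- make_training_set(batches[[4]], m = 2, n = 2)
tuned <- optimize_hyperparams(train, calib,
                              pso_config(n_particles = 10, n_iters = 25, seed = 1))
model <- fit_lssvm(bind_training_sets(list(train, calib)), tuned$hyper)
model
#> <lssvm: N=92 support values, sigma=6.424, C=2000, bias=18.31>
cat(sprintf("calibration MAPE: %.3f%%\n", 100 * mape(calib$y, predict(model, calib$X))))
#> calibration MAPE: 0.989%

# --- linearization at the last observed operating point
linearize_at(model, calib$X[nrow(calib$X), ])
#> <arx_model: n=2, m=1, dead_time=1, offset=1.489>
#>   a: -0.870353 -0.09545
#>   b: 0.204197 0.555354

# --- closed-loop GPC on the linear reference plant, two setpoint levels
gpc <- gpc_config(P = 5, L = 3, lam = 0.1, beta = 0.7,
                  u_min = 10, u_max = 55, du_max = 10)
log <- run_closed_loop(printed_plant(), gpc,
                       data.frame(start_step = c(1L, 181L), value = c(20, 35)),
                       steps = 360, init = list(u0 = 15, du0 = 4.5, y0 = 14.5))
evaluate_tracking(log)$segments
#>   start_step end_step setpoint max_abs_error_steady max_abs_error_settled settling_step
#> 1          1      180       20         0.000000e+00             0.0000000             8
#> 2        181      360       35         1.421085e-14             0.6799503           189
```

`run_closed_loop()` can also use a fitted LS-SVM model as the simulated
plant, or drive the Monod simulator itself with the LS-SVM supplying
the linearization at every step — see `?run_closed_loop` and the
methods vignette (`vignettes/methods.Rmd`).

`run_identification_study()` packages the full tuned-vs-default model
comparison (simulate, split, tune, fit, evaluate on an unseen test
batch) into one call.

## Command-line interface

A thin CLI wraps the pipeline stages
(`inst/cli/fermgpc.R`, installed under `system.file("cli", package = "fermgpc")`):

```sh
Rscript inst/cli/fermgpc.R simulate  --config cfg.json --seed 5 --out batches/
Rscript inst/cli/fermgpc.R fit       --train batches/ --hyper C=100,sigma=3 --out model.json
Rscript inst/cli/fermgpc.R tune      --train batches/ --seed 3 --out hyper.json
Rscript inst/cli/fermgpc.R linearize --model model.json --at state.json --out arx.json
Rscript inst/cli/fermgpc.R control   --gpc gpc.json --setpoints sp.csv --steps 360 --out log.csv
```

Batches are exchanged as `t,u,y` CSV files; models and ARX forms as
lossless (17-significant-digit) JSON.

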