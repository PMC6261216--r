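---
title: "Methods: LS-SVM identification and generalized predictive control of a fed-batch fermenter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LS-SVM identification and generalized predictive control of a fed-batch fermenter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermgpc)
```

# Scope

`fermgpc` implements a complete data-driven control toolchain for a
fed-batch bacterial fermentation process:

1. a **synthetic plant** — a Monod-kinetics fed-batch reactor used to
   generate training and validation batches;
2. **LS-SVM regression** with an RBF kernel, used as a one-step-ahead
   NARX model of bacteria concentration as a function of past substrate
   feed rates and past concentrations;
3. **particle swarm optimization** (PSO) of the two kernel
   hyperparameters;
4. **first-order Taylor linearization** of the fitted NARX model to a
   local ARX model;
5. a **generalized predictive controller** (GPC) in CARIMA increment
   form built on the linearized model;
6. a **closed-loop orchestrator** that ties model, linearizer and
   controller around a simulated plant.

This vignette records the mathematical form of each component, the
default parameter values with units, and the numerical and design
decisions that are not obvious from the code alone.

# The synthetic plant

## Model

The generator integrates standard unsegregated, unstructured fed-batch
mass balances with Monod growth:

$$
\frac{d(xV)}{dt} = \mu(s)\,xV, \qquad
\frac{d(sV)}{dt} = -\frac{\mu(s)}{Y_{x/s}}\,xV + F\,s_{\text{feed}},
\qquad
\frac{dV}{dt} = F,
$$

with $\mu(s) = \mu_{\max}\, s_+/(K_s + s_+)$, $s_+ = \max(s, 0)$. The
state is integrated in **extensive** variables (total biomass $X = xV$,
total substrate $S = sV$, volume $V$) rather than concentrations. The
reason is numerical: in extensive form the linear combination
$X + Y_{x/s} S$ has no forcing term when $F = 0$, and because
fixed-step Runge–Kutta integration is exact for linear invariants, the
biomass/substrate mass balance is conserved to machine precision
regardless of step size. The concentration form would only conserve it
to integration-error accuracy.

Integration uses classical fixed-step RK4 with 10 sub-steps per
sampling interval. A fixed-step scheme keeps every run bitwise
reproducible for a given seed; adaptive schemes trade that away for
accuracy the smooth Monod right-hand side does not need. Non-finite
state at any sub-step aborts with an error naming the failing interval.

Observation noise is additive Gaussian on the measured concentration,
drawn once per sampling instant from a caller-supplied seed.

## Defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `mu_max` | 0.3 | 1/h | maximum specific growth rate |
| `K_s` | 0.3 | g/L | Monod half-saturation constant |
| `Y_xs` | 0.5 | g/g | biomass yield on substrate |
| `s_feed` | 200 | g/L | substrate concentration in the feed |
| `V0` | 50 | L | initial broth volume |
| `x0` | 4 | g/L | initial biomass concentration |
| `s0` | 8 | g/L | initial substrate concentration |
| `noise_sd` | 0.05 | g/L | measurement noise standard deviation |
| `dt` | 1 | h | sampling interval |

## What the generator emulates — and what it does not

It emulates the dominant behaviour relevant to feed-rate control:
substrate-limited exponential growth, dilution by feeding, saturation
when substrate is exhausted, and measurement noise. It deliberately
omits oxygen transfer, temperature and pH dynamics, maintenance
metabolism, substrate inhibition, product formation, death kinetics and
sensor dynamics. It is a *training-data factory* for the identification
pipeline, not a digital twin of any particular organism or reactor.

## Time alignment

A batch stores `u[k]` as the feed rate applied over the interval
starting at `t[k]`; the final entry is `NA` because no interval follows
the last sample. Lagged regressor windows built by
`make_training_set()` therefore never touch the `NA`, and windows never
span batch boundaries when batches are combined.

# LS-SVM regression

## Formulation

For training pairs $(\mathbf{x}_i, y_i)$, $i = 1 \dots N$, LS-SVM
regression with regularization constant $C$ solves the KKT system

$$
\begin{bmatrix} 0 & \mathbf{1}^\top \\ \mathbf{1} & \Gamma + C^{-1} I \end{bmatrix}
\begin{bmatrix} \delta \\ \boldsymbol\alpha \end{bmatrix}
=
\begin{bmatrix} 0 \\ \mathbf{y} \end{bmatrix},
\qquad
\Gamma_{ij} = K(\mathbf{x}_i, \mathbf{x}_j),
$$

a single dense linear solve — no quadratic program. The predictor is
$f(\mathbf{x}) = \sum_i \alpha_i K(\mathbf{x}, \mathbf{x}_i) + \delta$.
The kernel is the RBF

$$K(\mathbf{x}_1, \mathbf{x}_2) = \exp\!\left(-\lVert \mathbf{x}_1 - \mathbf{x}_2 \rVert^2 / \sigma^2\right),$$

with $\sigma^2$ (not $2\sigma^2$) in the denominator; the convention is
absorbed into the tuned $\sigma$ either way, but it is fixed here so
that serialized models are unambiguous.

Two structural facts are exploited as invariants in the test suite: the
first KKT row forces $\sum_i \alpha_i = 0$, and the residuals satisfy
$e_i = \alpha_i / C$.

## Numerical choices

* **Feature standardization.** Regressors mix feed rates (order 1 L/h)
  and concentrations (order 10 g/L); an isotropic RBF on raw features
  would let the large-scale coordinate dominate. Each feature is
  centred and scaled to unit variance at fit time; the centre/scale
  vectors are stored on the model so prediction, gradient and
  serialization are self-contained.
* **Conditioning guard.** The KKT matrix is solved with a dense
  LU solve after an estimated condition number check; beyond `1e12` the
  fit falls back to a Moore–Penrose pseudo-inverse (`MASS::ginv`),
  warns, and flags the model. Large `C` with near-duplicate rows makes
  this reachable in practice during PSO exploration.
* **Gram symmetry.** Pairwise squared distances are computed by the
  usual $\lVert a \rVert^2 + \lVert b \rVert^2 - 2ab$ expansion and
  clamped below at zero before exponentiation.

## NARX structure

The regressor for one-step-ahead prediction is

$$\mathbf{x}(t) = [\,u(t-1), \dots, u(t-m),\; y(t-1), \dots, y(t-n)\,],$$

with $m = n = 2$ as the working default order — small enough that the
linearized model stays low-order for the controller, large enough to
capture the dominant second-order response of the reactor around an
operating point. Model error is reported as RMSE, maximum absolute
error and MAPE.

# PSO hyperparameter tuning

The fitness of a candidate $(C, \sigma)$ is the MAPE of the model
fitted on the training batches and evaluated on a *held-out calibration
batch* — never on the training data itself, which large $C$ can
interpolate arbitrarily well. A fit failure scores `Inf` so the swarm
simply routes around pathological corners of the search box.

Defaults: 20 particles, 150 iterations, cognitive weight $c_1 = 1.5$,
social weight $c_2 = 1.7$, inertia decaying linearly from 0.9 to 0.4,
search box $C \in [10^{-3}, 2000]$, $\sigma \in [0.01, 100]$. The lower
bound on $C$ is strictly positive because $C^{-1}$ appears in the KKT
system. Velocities are clamped to 20 % of each box width; positions are
clamped to the box with the corresponding velocity component zeroed, a
standard absorbing-boundary rule that keeps particles from oscillating
against a wall. Initial guesses (e.g. the untuned default) can be
seeded into the swarm via `init_guesses`, which guarantees the tuned
result is never worse than the seed on the calibration fitness. The
global-best trace is recorded per iteration and is monotone by
construction.

# Linearization to ARX form

Around the current lag vector $\mathbf{x}_0$ the predictor is expanded
to first order, $f(\mathbf{x}) \approx f(\mathbf{x}_0) + \mathbf{g}^\top
(\mathbf{x} - \mathbf{x}_0)$, with the gradient computed analytically:
each RBF term contributes $\alpha_i K(\mathbf z, \mathbf z_i) \cdot
(-2/\sigma^2)(\mathbf z - \mathbf z_i)$ on the standardized scale,
chain-ruled through the stored per-feature scaling. Collecting lags
gives the affine ARX model

$$
y(t) = -\sum_{i=1}^{n} a_i\, y(t-i) + \sum_{j=1}^{m} b_j\, u(t-j) + c,
\qquad
a_i = -\frac{\partial f}{\partial y(t-i)},\;
b_j = \frac{\partial f}{\partial u(t-j)},\;
c = f(\mathbf{x}_0) - \mathbf{g}^\top \mathbf{x}_0,
$$

which agrees with the LS-SVM exactly at $\mathbf{x}_0$. The analytic
gradient is verified against central finite differences in the tests;
the Taylor remainder is verified to shrink quadratically.

## Sign convention

Throughout the package the ARX container stores the *A-polynomial*
coefficients of the shift-operator form
$A(z^{-1}) y(t) = B(z^{-1}) u(t-d) + c$ with
$A(z^{-1}) = 1 + a_1 z^{-1} + \dots$ — so the simulation recursion
**subtracts** $a_i y(t-i)$. This is the convention under which CARIMA
GPC formulas are conventionally written, and it is applied uniformly:
the reference plant, the linearizer output, the step-coefficient
computation and the free-response forecast all share one container and
one recursion, which removes an entire class of sign bugs. The built-in
reference plant `printed_plant()` stores $a_1 = -0.435$, i.e. its
recursion is $y(k) = 0.673\,u(k) + 0.109\,u(k-1) + 0.435\,y(k-1)$, a
stable pole at $0.435$ with static gain
$(0.673 + 0.109)/(1 - 0.435) \approx 1.384$, which places both
operating setpoints used in the examples (20 and 35 g/L) inside the
statically reachable band for $u \in [10, 55]$ L/h.

# Generalized predictive control

## Formulation

The linearized model is embedded in CARIMA form and the predicted
outputs over the costing horizon are split as
$\mathbf{\hat y} = G\, \Delta \mathbf{u} + \mathbf{f}$:

* the **step coefficients** $g_0, g_1, \dots$ are obtained by simulating
  the ARX recursion against a unit step from zero initial conditions
  with the offset suppressed (the offset belongs to the free response,
  not to the incremental dynamics);
* $G$ is the lower-triangular $P \times L$ Toeplitz matrix of step
  coefficients;
* the **free response** $\mathbf{f}$ is the forecast with the input
  frozen at its last applied value, offset included, anchored at the
  *measured* output — the anchor is what makes tracking offset-free on
  a matched plant, because any model/plant mismatch enters the forecast
  as a measured disturbance at every step.

Minimizing
$J = \sum_{j=N_1}^{N_2} (\hat y(t+j) - w(t+j))^2 + \lambda \sum_{j=1}^{L} \Delta u(t+j-1)^2$
gives the unconstrained increment
$\Delta u(t) = \mathbf{d}^\top (\mathbf{w} - \mathbf{f})$ with
$\mathbf{d}^\top$ the first row of $(G^\top G + \lambda I)^{-1} G^\top$
restricted to the costing window; only the first increment is applied
(receding horizon). The reference trajectory is the first-order filter
$w(t+j) = \beta\, w(t+j-1) + (1-\beta)\, y_s$ seeded at the current
measurement, which softens setpoint steps.

Defaults: prediction horizon $P = 5$, control horizon $L = 3$, move
penalty $\lambda = 0.1$, reference smoothing $\beta = 0.7$. These
horizons are short because the linearization is only locally valid; a
long horizon would cost accuracy where the affine model is least
trustworthy.

## Constraints

Amplitude and rate constraints ($u_{\min} \le u \le u_{\max}$,
$|\Delta u| \le \Delta u_{\max}$) are enforced by **clamping** the
unconstrained increment — first the rate, then the amplitude, then the
increment is recomputed for the log. A constrained QP would be the
exact treatment; clamping was chosen because with a single applied
increment per step the two coincide whenever at most one constraint is
active, the receding horizon re-optimizes every step anyway, and the
clamp keeps the controller a closed-form linear law that is trivially
verifiable against independent least-squares and `optim` oracles in the
tests. If $\lambda = 0$ makes $G^\top G$ singular the solve fails with
an error pointing at `lam`.

# Closed loop

`run_closed_loop()` supports three plant modes:

1. the built-in linear reference plant (fixed ARX model, no
   re-linearization needed);
2. a fitted LS-SVM model acting as the plant via its own NARX recursion
   (self-consistency studies), re-linearized every
   `relinearize_every` steps;
3. the Monod simulator stepped one sampling interval at a time, with a
   fitted LS-SVM model supplying the linearization (the full
   model-plant-mismatch scenario).

Re-linearizing every step is the default: the gradient is analytic and
cheap, and a stale linearization is the main way a kernel model's local
validity is lost. The option to hold it for several steps exists to
study exactly that degradation.

`evaluate_tracking()` reports, per setpoint segment, the worst absolute
error over the final third of the segment (steady-band error), the
worst error from the first setpoint crossing onward (settling-phase
error; a monotone approach that never crosses is measured from its
entry into the 2 % band), the 2 % settling step, and the count of
constraint violations.

One property test deserves a note: the *offset-free tracking sweep*
runs the controller against the matched reference plant over a grid of
constant setpoints **with the amplitude constraints released**. The
point of that test is the asymptotic property of the increment-form
law, which only holds when the setpoint is statically reachable;
re-imposing the actuator box would turn an algebraic property into a
reachability question and test nothing about the controller.

# Identification study

`run_identification_study()` reproduces the headline comparison of the
toolchain: simulate a set of batches under randomized piecewise-constant
feed profiles (4-hour blocks, uniform on [0.1, 1.2] L/h), fit an
LS-SVM with default hyperparameters and one with PSO-tuned
hyperparameters (training batches 1..N−2, calibration batch N−1), and
compare RMSE / maximum error / MAPE on the unseen test batch N. The
default hyperparameters are seeded into the swarm, so the tuned model
can only lose on the test batch through calibration/test disagreement;
the report records a `tuned_no_worse` flag and warns rather than errors
in that event, since it is a property of the data split, not a bug.

Problem sizes throughout (10 batches × 24 h, 20 particles × 150
iterations, 360-step closed-loop runs) are this package's own working
defaults: large enough that the comparisons are out-of-sample and the
closed loop reaches steady state twice, small enough that the full test
suite runs in well under a minute.

# Serialization

Models (`write_lssvm_json` / `read_lssvm_json`) and ARX forms
(`write_arx_json` / `read_arx_json`) round-trip through JSON with
17-significant-digit numeric output, which is lossless for IEEE
doubles; matrices are written row-major. Batches round-trip through a
three-column CSV (`t,u,y`).
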