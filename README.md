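# isingcsd

Critical-slowing-down tools for predicting critical transitions, built
around two representations of the Ising model. The package is for
modellers who want to test transition-prediction methods on systems where
the ground truth is known: it provides an equation-based (mean-field) and
an agent-based (2D lattice Metropolis) simulator with saddle-node and
pitchfork regimes, an active perturbation–recovery estimator of the
bifurcation point, and the classical passive early-warning-signal (EWS)
indicator suite for comparison.

## The method

Dynamics. The mean-field magnetization follows

    M[t+1] = M[t] + (-M[t] + tanh(J*M[t] + H)) * dt + sigma * N[t]

with `dt = 0.1`, coupling `J = T` by default and per-step standard-normal
noise `N`. Driving `T` at `H = 0` gives a pitchfork at `T = 1`; driving
`H` at fixed `T > 1` gives saddle-node folds at
`|H*| = J*sqrt(1 - 1/J) - arccosh(sqrt(J))` (±0.619 at `T = 2.12`). The
lattice model updates spins by Metropolis dynamics with flip energy
`Ediff = 2*S*(NB - H)` in a von Neumann neighborhood with periodic
boundaries.

Estimation. At each of k ≥ 2 values of the driven parameter, the system
is simulated through a 100-step transient, perturbed for one time step,
and its ensemble-mean recovery recorded (100 realizations). The
first-order differences of each mean recovery curve are polynomial-fitted
over the pre-equilibrium segment; the fitted maxima `m_i` — the maximal
recovery rates — are regressed linearly on the parameter values `c_i` and
the line is extended to the zero line. The crossing

    c_hat = -intercept / slope

is the parameter value at which recovery would cease: the estimated
bifurcation point. Near a fold the minimal recovery speed is linear in
the distance to the bifurcation, which is what makes the linear
extrapolation exact to first order.

## Worked example

Estimate the lower saddle-node fold of the mean-field model at
`T = 2.12` from four perturbation ensembles placed below the bistable
window (amplitude 1.5, transient 100 steps, 100 realizations, noise
0.01):

```r
library(isingcsd)

fold_points(2.12)
#>      lower      upper
#> -0.6189054  0.6189054

cfg <- experiment_config("ebm", "saddle",
  values = fold_points(2.12)[["lower"]] - c(0.20, 0.15, 0.10, 0.05),
  temperature = 2.12, amplitude = 1.5, transient = 100,
  recovery_length = 400, realizations = 100, sigma = 0.01, seed = 1)
est <- run_prediction_experiment(cfg)
est
#> <bifurcation_estimate>
#>   c_hat = -0.619992  (slope 0.04518, intercept 0.02801, R^2 0.9670, k = 4)

tidy(est)
#> # A tibble: 4 × 4
#>        c        m t_star y_star
#>    <dbl>    <dbl>  <dbl>  <dbl>
#> 1 -0.819 -0.00941   39.0  0.774
#> 2 -0.769 -0.00637   46.4  0.754
#> 3 -0.719 -0.00391   58.4  0.744
#> 4 -0.669 -0.00270   67.1  0.767
```

Reading the output: the maximal recovery rates `m` shrink toward zero as
the perturbation field approaches the fold — critical slowing down — and
their zero-line extrapolation `c_hat = -0.620` reproduces the analytic
fold at −0.619 to 0.2%. The `y_star` column shows each maximum occurring
at magnetizations near 0.75, the "ghost" of the fold equilibrium at
0.727, where recovery is slowest. `autoplot(est)` draws the
maxima-versus-parameter extrapolation; `glance(est)` returns the
regression summary as a one-row tibble.

The same pipeline runs on the lattice model (`model = "abm"`, alignment
perturbations `r`) and on the pitchfork scenario (driven temperature,
`direction = "below"` or `"above"`), and `rolling_ews()` computes the
passive indicator traces (AR1, STD, S, K, DFA, FR) over rolling windows
for any trajectory.

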