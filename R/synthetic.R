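#' Saddle-node normal form
#'
#' Euler iteration of \eqn{x_{t+1} = x_t + (a - x_t^2)\,dt + \sigma N},
#' the canonical fold system: for `a > 0` a stable equilibrium at
#' \eqn{+\sqrt{a}} and an unstable one at \eqn{-\sqrt{a}}, colliding at
#' `a = 0`. Because the maximal recovery speed through the region below
#' the stable point is exactly `a`, the fold position is known analytically
#' and the system serves as the oracle for the whole estimation pipeline.
#'
#' @param a fold parameter.
#' @param dt time step, default 0.01.
#' @param n_steps number of steps.
#' @param x0 initial state.
#' @param sigma per-step noise standard deviation (default 0).
#' @param seed RNG seed or `NULL`.
#'
#' @return An [new_trajectory()] tibble.
#' @export
simulate_saddle_normal_form <- function(a, dt = 0.01, n_steps = 1000, x0,
                                        sigma = 0, seed = NULL) {
  if (dt <= 0) abort("`dt` must be > 0.")
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(n_steps + 1)
  x[1] <- x0
  noise <- if (sigma > 0) rnorm(n_steps) else numeric(n_steps)
  for (t in seq_len(n_steps)) {
    x[t + 1] <- x[t] + (a - x[t]^2) * dt + sigma * noise[t]
    if (!is.finite(x[t + 1]) || abs(x[t + 1]) > 1e6) {
      abort(sprintf("normal form diverged at step %d (left the basin).", t))
    }
  }
  new_trajectory(x,
    dt = dt, parameter_name = "a", parameter_values = a,
    seed = seed, model = "saddle_normal_form"
  )
}

#' Simulate a stationary AR(1) process
#'
#' \eqn{x_t = \phi x_{t-1} + \sigma \epsilon_t} started from its
#' stationary distribution; the null fixture for the indicator suite.
#'
#' @param phi autoregressive coefficient, `|phi| < 1`.
#' @param sigma innovation standard deviation.
#' @param n series length.
#' @param seed RNG seed or `NULL`.
#'
#' @return Numeric vector of length `n`.
#' @export
simulate_ar1 <- function(phi, sigma = 1, n, seed = NULL) {
  if (abs(phi) >= 1) abort("`phi` must satisfy |phi| < 1.")
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1, sd = sigma / sqrt(1 - phi^2))
  innov <- rnorm(n - 1, sd = sigma)
  for (t in seq.int(2L, n)) x[t] <- phi * x[t - 1] + innov[t - 1]
  x
}
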