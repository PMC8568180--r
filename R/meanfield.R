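#' Mean-field Ising model configuration
#'
#' The mean-field (equation-based) representation replaces neighbor
#' interactions by coupling to the average state, yielding the scalar
#' stochastic difference equation
#' \deqn{M_{t+1} = M_t + (-M_t + \tanh(J M_t + H))\,\Delta t + \sigma N_t,}
#' with coupling \eqn{J} defaulting to the temperature \eqn{T} and
#' \eqn{N_t} a standard-normal draw. With the parameter \eqn{T} driven at
#' \eqn{H = 0} the deterministic part undergoes a pitchfork bifurcation at
#' \eqn{T = 1}; with \eqn{H} driven at fixed \eqn{T > 1} it shows a pair of
#' saddle-node bifurcations and hysteresis.
#'
#' @param temperature temperature \eqn{T} (dimensionless); the coupling in
#'   the `tanh` argument unless `coupling` is given.
#' @param field external field \eqn{H}; a scalar, or a vector of length
#'   `n_steps` giving a per-step schedule (ramp).
#' @param dt time-step size \eqn{\Delta t}, default 0.1.
#' @param sigma noise weight \eqn{\sigma \ge 0}; the per-step standard
#'   deviation of the additive Gaussian noise (no \eqn{\sqrt{\Delta t}}
#'   scaling).
#' @param n_steps number of update steps (the trajectory has
#'   `n_steps + 1` states).
#' @param m0 initial magnetization, in \[-1.5, 1.5\].
#' @param seed RNG seed (integer) or `NULL`.
#' @param coupling effective coupling \eqn{J} in the `tanh` argument.
#'   Defaults to `temperature`; exposed because alternative mean-field
#'   parametrizations in the literature scale the argument differently.
#'
#' @return A list of class `meanfield_config`.
#' @export
meanfield_config <- function(temperature, field = 0, dt = 0.1, sigma = 0,
                             n_steps = 1000, m0 = 0, seed = NULL,
                             coupling = NULL) {
  if (dt <= 0) abort("`dt` must be > 0.")
  if (sigma < 0) abort("`sigma` must be >= 0.")
  if (n_steps < 1) abort("`n_steps` must be >= 1.")
  if (abs(m0) > 1.5) abort("`m0` must lie in [-1.5, 1.5].")
  if (!length(field) %in% c(1L, n_steps)) {
    abort("`field` must be a scalar or a per-step schedule of length `n_steps`.")
  }
  structure(
    list(
      temperature = temperature, field = field, dt = dt, sigma = sigma,
      n_steps = as.integer(n_steps), m0 = m0, seed = seed,
      coupling = if (is.null(coupling)) temperature else coupling
    ),
    class = "meanfield_config"
  )
}

#' Single Euler step of the mean-field model
#'
#' @param m current magnetization.
#' @param cfg a [meanfield_config()]; a scalar `field` is used as-is.
#' @param noise_draw a standard-normal variate (0 for the deterministic
#'   skeleton).
#'
#' @return The next magnetization value,
#'   `m + (-m + tanh(coupling * m + H)) * dt + sigma * noise_draw`.
#' @export
step_meanfield <- function(m, cfg, noise_draw = 0) {
  H <- cfg$field[1]
  m + (-m + tanh(cfg$coupling * m + H)) * cfg$dt + cfg$sigma * noise_draw
}

# Vectorized over an ensemble of states; `H` scalar. Internal workhorse.
mf_step <- function(m, coupling, H, dt, sigma, noise) {
  m + (-m + tanh(coupling * m + H)) * dt + sigma * noise
}

#' Simulate the mean-field Ising model
#'
#' Iterates the mean-field difference equation for `n_steps` steps from
#' `m0`, with optional per-step field schedule and additive Gaussian noise.
#'
#' @param cfg a [meanfield_config()].
#'
#' @return An [new_trajectory()] tibble of length `n_steps + 1` with the
#'   driven parameter recorded per state.
#' @export
#'
#' @examples
#' cfg <- meanfield_config(temperature = 0.5, n_steps = 200, m0 = 0.8)
#' traj <- simulate_meanfield(cfg)
#' tail(traj$state, 1)  # decays toward the unique equilibrium at 0
simulate_meanfield <- function(cfg) {
  stopifnot(inherits(cfg, "meanfield_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_steps
  H <- if (length(cfg$field) == 1L) rep(cfg$field, n) else cfg$field
  values <- numeric(n + 1)
  values[1] <- cfg$m0
  noise <- if (cfg$sigma > 0) rnorm(n) else numeric(n)
  m <- cfg$m0
  for (t in seq_len(n)) {
    m <- mf_step(m, cfg$coupling, H[t], cfg$dt, cfg$sigma, noise[t])
    if (!is.finite(m)) {
      abort(sprintf(
        "mean-field state diverged (non-finite) at step %d; check parameters.", t
      ))
    }
    values[t + 1] <- m
  }
  new_trajectory(values,
    dt = cfg$dt, parameter_name = "H",
    parameter_values = c(H[1], H), seed = cfg$seed, model = "meanfield"
  )
}

# Ensemble variant: evolves `realizations` states in parallel at fixed
# parameters; returns a (n_steps+1) x R matrix. Used by the
# perturbation-recovery machinery, which always averages many realizations.
simulate_meanfield_ensemble <- function(m0, n_steps, coupling, H, dt, sigma,
                                        realizations) {
  H <- rep(H, length.out = n_steps)
  m <- rep(m0, length.out = realizations)
  out <- matrix(NA_real_, n_steps + 1, realizations)
  out[1, ] <- m
  for (t in seq_len(n_steps)) {
    noise <- if (sigma > 0) rnorm(realizations) else 0
    m <- mf_step(m, coupling, H[t], dt, sigma, noise)
    out[t + 1, ] <- m
  }
  if (!all(is.finite(out))) abort("mean-field ensemble diverged (non-finite state).")
  out
}

#' Deterministic equilibria of the mean-field model
#'
#' Finds all real roots of the self-consistency equation
#' \eqn{M = \tanh(J M + H)} on \[-1, 1\] by dense sign-change bracketing
#' (step 1e-3) followed by root polishing to machine precision, and
#' classifies each root: stable iff \eqn{-1 + J\,\mathrm{sech}^2(J M^* + H) < 0}.
#'
#' @param temperature temperature \eqn{T} (> 0).
#' @param field external field \eqn{H}.
#' @param coupling effective coupling, defaults to `temperature`.
#'
#' @return A tibble with columns `state` and `stability`
#'   (`"stable"`/`"unstable"`), sorted by `state`; 1 or 3 rows.
#' @export
meanfield_equilibria <- function(temperature, field = 0, coupling = NULL) {
  if (temperature <= 0) abort("`temperature` must be > 0.")
  J <- if (is.null(coupling)) temperature else coupling
  f <- function(m) tanh(J * m + field) - m
  grid <- seq(-1, 1, by = 1e-3)
  fg <- f(grid)
  roots <- numeric(0)
  exact <- which(fg == 0)
  roots <- c(roots, grid[exact])
  sgn <- sign(fg)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    r <- uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-15)$root
    # Newton polish so the residual meets the 1e-9 contract comfortably
    for (k in 1:3) {
      fp <- J / cosh(J * r + field)^2 - 1
      if (abs(fp) < 1e-12) break
      r <- r - f(r) / fp
    }
    roots <- c(roots, r)
  }
  roots <- sort(unique(round(roots, 12)))
  # collapse near-duplicates from grid points hitting roots exactly
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) > 1e-9)
    roots <- roots[keep]
  }
  stab <- ifelse(-1 + J / cosh(J * roots + field)^2 < 0, "stable", "unstable")
  tibble::tibble(state = roots, stability = stab)
}

#' Saddle-node (fold) points of the mean-field model
#'
#' For coupling \eqn{J > 1} the mean-field equation is bistable over a
#' symmetric window of the external field. The folds, where a stable and
#' the unstable root collide, have the closed form
#' \deqn{|H^*| = J\sqrt{1 - 1/J} - \mathrm{arccosh}(\sqrt{J}).}
#'
#' @inheritParams meanfield_equilibria
#'
#' @return Named numeric vector `c(lower = -|H*|, upper = +|H*|)`.
#' @export
#'
#' @examples
#' fold_points(2.12)  # c(lower = -0.619, upper = 0.619)
fold_points <- function(temperature, coupling = NULL) {
  J <- if (is.null(coupling)) temperature else coupling
  if (J <= 1) abort("no bistable region: coupling must exceed 1.")
  h <- J * sqrt(1 - 1 / J) - acosh(sqrt(J))
  c(lower = -h, upper = h)
}

#' Equilibrium branches over a parameter grid
#'
#' Traces the deterministic equilibrium curve of the mean-field model over
#' a grid of the driven parameter, split into branches suitable for
#' overplotting on simulation data.
#'
#' For `parameter = "H"` (fixed temperature) the branches are `"lower"`,
#' `"middle"` (unstable) and `"upper"`, delimited by [fold_points()]. For
#' `parameter = "T"` (fixed field, the pitchfork scan) roots are labelled
#' `"lower"`/`"middle"`/`"upper"` per grid point by their ordering.
#'
#' @param temperature fixed temperature (used when `parameter = "H"`).
#' @param parameter_grid sorted numeric grid of the driven parameter.
#' @param parameter which parameter varies, `"H"` or `"T"`.
#' @param field fixed field (used when `parameter = "T"`).
#' @param coupling effective coupling override (`parameter = "H"` only).
#'
#' @return A tibble with columns `parameter`, `state`, `stability`, `branch`.
#' @export
equilibrium_curves <- function(temperature = NULL, parameter_grid,
                               parameter = c("H", "T"), field = 0,
                               coupling = NULL) {
  parameter <- match.arg(parameter)
  if (is.unsorted(parameter_grid)) abort("`parameter_grid` must be sorted.")
  rows <- purrr::map(parameter_grid, function(p) {
    eq <- if (parameter == "H") {
      meanfield_equilibria(temperature, field = p, coupling = coupling)
    } else {
      meanfield_equilibria(p, field = field, coupling = coupling)
    }
    eq$parameter <- p
    k <- nrow(eq)
    eq$branch <- if (k == 3) {
      c("lower", "middle", "upper")
    } else if (parameter == "H") {
      J <- if (is.null(coupling)) temperature else coupling
      if (J > 1) {
        fp <- fold_points(temperature, coupling = coupling)
        if (p <= fp[["lower"]]) "lower" else if (p >= fp[["upper"]]) "upper" else "middle"
      } else {
        "middle"
      }
    } else {
      "middle"
    }
    eq
  })
  dplyr::bind_rows(rows)[, c("parameter", "state", "stability", "branch")]
}
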