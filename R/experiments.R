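#' Ensemble sweep summary
#'
#' Runs many realizations of a parameter sweep of either model and
#' summarises the magnetization per recorded step: min, mean, max and the
#' across-realization standard deviation. This is the data view on which
#' the noise levels of the two model representations are compared.
#'
#' @param model `"ebm"` (mean-field) or `"abm"` (lattice).
#' @param scenario `"saddle"` (driven field, fixed temperature) or
#'   `"pitchfork"` (driven temperature, zero field).
#' @param from,to sweep endpoints of the driven parameter; defaults per
#'   model and scenario (saddle: field -0.2 to 0.2; pitchfork: temperature
#'   around the respective critical value).
#' @param length number of recorded steps (default 500).
#' @param realizations ensemble size (default 100).
#' @param temperature fixed temperature for the saddle scenario.
#' @param sigma mean-field noise weight.
#' @param L lattice side; `L_random = TRUE` redraws it per realization
#'   from \{50, 100\}.
#' @param L_random see `L`.
#' @param dt mean-field time step.
#' @param equilibrate steps (sweeps) run at the initial parameter value
#'   before recording starts.
#' @param start which branch/state the sweep starts on: `"lower"`/`"upper"`
#'   for the mean-field, `"down"`/`"up"`/`"random"` for the lattice.
#' @param coupling mean-field coupling override.
#' @param seed base seed; realization i uses `seed + i`.
#'
#' @return A `sweep_summary` tibble with columns `step`, `parameter`,
#'   `min`, `mean`, `max`, `sd`.
#' @export
run_sweep_summary <- function(model = c("ebm", "abm"),
                              scenario = c("saddle", "pitchfork"),
                              from = NULL, to = NULL, length = 500,
                              realizations = 100, temperature = 2.12,
                              sigma = 0.01, L = 100, L_random = FALSE,
                              dt = 0.1, equilibrate = 100,
                              start = NULL, coupling = NULL, seed = 1) {
  model <- match.arg(model)
  scenario <- match.arg(scenario)
  if (is.null(from) || is.null(to)) {
    rng <- sweep_default_range(model, scenario)
    if (is.null(from)) from <- rng[1]
    if (is.null(to)) to <- rng[2]
  }
  sched <- seq(from, to, length.out = length)
  if (model == "ebm") {
    cp <- if (is.null(coupling)) temperature else coupling
    states <- matrix(NA_real_, length, realizations)
    if (scenario == "saddle") {
      if (is.null(start)) start <- "upper"
      eq <- meanfield_equilibria(temperature, from, coupling = cp)
      stable <- eq$state[eq$stability == "stable"]
      m0 <- if (start == "lower") min(stable) else max(stable)
      for (r in seq_len(realizations)) {
        set.seed(seed + r)
        m <- simulate_meanfield_ensemble(m0, equilibrate, cp, from, dt, sigma, 1)
        tr <- simulate_meanfield_ensemble(m[equilibrate + 1, 1], length - 1,
          cp, sched[-1], dt, sigma, 1)
        states[, r] <- tr[, 1]
      }
    } else {
      m0 <- if (is.null(start)) 1e-3 else if (start == "lower") -1 else 1
      for (r in seq_len(realizations)) {
        set.seed(seed + r)
        # coupling follows the driven temperature in the pitchfork scan
        m <- m0
        out <- numeric(length)
        noise <- if (sigma > 0) rnorm(equilibrate + length - 1) else
          numeric(equilibrate + length - 1)
        for (t in seq_len(equilibrate)) {
          m <- mf_step(m, sched[1], 0, dt, sigma, noise[t])
        }
        out[1] <- m
        for (t in seq_len(length - 1)) {
          m <- mf_step(m, sched[t + 1], 0, dt, sigma, noise[equilibrate + t])
          out[t + 1] <- m
        }
        states[, r] <- out
      }
    }
  } else {
    states <- matrix(NA_real_, length, realizations)
    if (is.null(start)) start <- if (scenario == "saddle") "up" else "random"
    for (r in seq_len(realizations)) {
      set.seed(seed + r)
      Lr <- if (L_random) sample(c(50L, 100L), 1) else L
      lat <- switch(start,
        up = lattice_uniform(Lr, 1L),
        down = lattice_uniform(Lr, -1L),
        random = lattice_random(Lr)
      )
      if (scenario == "saddle") {
        Ts <- rep(temperature, equilibrate + length)
        Hs <- c(rep(from, equilibrate), sched)
      } else {
        Ts <- c(rep(from, equilibrate), sched)
        Hs <- rep(0, equilibrate + length)
      }
      res <- cpp_simulate_lattice(lat, Ts, Hs, 1L, -1L, -1L)
      states[, r] <- res$magnetization[(equilibrate + 1):(equilibrate + length)]
    }
  }
  out <- tibble::tibble(
    step = seq_len(length),
    parameter = sched,
    min = apply(states, 1, min),
    mean = rowMeans(states),
    max = apply(states, 1, max),
    sd = apply(states, 1, sd)
  )
  structure(out,
    class = c("sweep_summary", class(out)),
    model = model, scenario = scenario, temperature = temperature,
    sigma = sigma, L = L, realizations = realizations, seed = seed
  )
}

sweep_default_range <- function(model, scenario) {
  if (scenario == "saddle") {
    c(-0.2, 0.2)
  } else if (model == "ebm") {
    c(0.5, 1.5)
  } else {
    c(1.5, 3.0)
  }
}

# indices of the pre-transition plateau: steps before the ensemble mean
# departs from its initial level by more than `frac` of the total swing
plateau_indices <- function(summary, frac = 0.05) {
  m <- summary$mean
  m0 <- median(m[seq_len(max(3, floor(0.05 * length(m))))])
  swing <- diff(range(m))
  dep <- which(abs(m - m0) > frac * swing)
  end <- if (length(dep)) dep[1] - 1L else length(m)
  seq_len(max(end, 2L))
}

#' Calibrate the mean-field noise weight against target data
#'
#' Selects, from a grid of candidate noise weights, the \eqn{\sigma} whose
#' mean-field across-realization standard deviation best matches the
#' target summary's on the pre-transition plateau (the sweep portion
#' before the ensemble mean departs from its initial level).
#'
#' @param target_summary a [run_sweep_summary()] result (typically from
#'   the lattice model).
#' @param sigma_grid candidate noise weights.
#' @param temperature fixed temperature of the comparison runs.
#' @param dt,coupling mean-field parameters.
#' @param realizations ensemble size for the mean-field runs; defaults to
#'   the target's.
#' @param plateau_frac plateau detection threshold, as a fraction of the
#'   sweep's total magnetization swing.
#' @param seed base seed.
#'
#' @return A list of class `sigma_calibration` with elements `sigma` (the
#'   best grid value), `table` (per-candidate comparison) and `plateau`
#'   (step indices used).
#' @export
calibrate_sigma <- function(target_summary, sigma_grid, temperature = 2.12,
                            dt = 0.1, coupling = NULL, realizations = NULL,
                            plateau_frac = 0.05, seed = 1) {
  if (!length(sigma_grid)) abort("`sigma_grid` must be nonempty.")
  stopifnot(inherits(target_summary, "sweep_summary"))
  if (is.null(realizations)) {
    realizations <- attr(target_summary, "realizations")
  }
  plat <- plateau_indices(target_summary, plateau_frac)
  target_sd <- mean(target_summary$sd[plat])
  sched <- target_summary$parameter[plat]
  cp <- if (is.null(coupling)) temperature else coupling
  # run the mean-field on the plateau schedule, on the stable branch whose
  # sign matches the target's plateau state
  branch_sign <- sign(mean(target_summary$mean[plat]))
  eq <- meanfield_equilibria(temperature, sched[1], coupling = cp)
  stable <- eq$state[eq$stability == "stable"]
  cand <- stable[sign(stable) == branch_sign]
  m0 <- if (length(cand)) cand[which.max(abs(cand))] else stable[which.max(abs(stable))]
  ebm_sd <- purrr::map_dbl(sigma_grid, function(s) {
    set.seed(seed)
    tr <- simulate_meanfield_ensemble(
      m0, length(sched), cp, c(sched[1], sched[-1]), dt, s, realizations
    )
    mean(apply(tr[-1, , drop = FALSE], 1, sd))
  })
  tab <- tibble::tibble(
    sigma = sigma_grid, ebm_sd = ebm_sd, target_sd = target_sd,
    abs_diff = abs(ebm_sd - target_sd)
  )
  structure(
    list(
      sigma = sigma_grid[which.min(tab$abs_diff)],
      table = tab, plateau = plat
    ),
    class = "sigma_calibration"
  )
}

#' @export
print.sigma_calibration <- function(x, ...) {
  cat(sprintf(
    "<sigma_calibration> best sigma = %g (target sd %.4g over %d plateau steps)\n",
    x$sigma, x$table$target_sd[1], length(x$plateau)
  ))
  print(x$table)
  invisible(x)
}

#' Prediction experiment configuration
#'
#' Bundles everything needed for one end-to-end transition-prediction run:
#' the model representation, the bifurcation scenario, the perturbation
#' plan and the estimator settings. Scenario and parameters must be
#' consistent: the saddle-node scenario drives the external field at fixed
#' temperature (default 2.12); the pitchfork scenario drives the
#' temperature at zero field.
#'
#' @param model `"ebm"` or `"abm"`.
#' @param scenario `"saddle"` or `"pitchfork"`.
#' @param values perturbation parameter values (>= 2).
#' @param temperature fixed temperature (saddle scenario).
#' @param field fixed field (pitchfork scenario; must be 0).
#' @param amplitude state-set perturbation amplitude (ebm). Defaults: the
#'   alternative equilibrium (+1) for the saddle scenario; for the
#'   pitchfork, 1 when approaching from below the transition and 0.01 from
#'   above.
#' @param r alignment probability (abm); default 0.
#' @param direction `"below"` or `"above"`: the side of the transition the
#'   perturbation values sit on (pitchfork scenario).
#' @param transient,recovery_length,realizations,seed see
#'   [perturbation_spec()].
#' @param sigma,dt,coupling mean-field parameters.
#' @param L,L_random,record_every lattice parameters.
#' @param start branch occupied before perturbation; defaults per scenario.
#' @param degree polynomial degree for [fit_slope()]. The experiment
#'   default is 8: the ensemble difference curves produced by large
#'   within-basin perturbations have a boundary-layer / plateau / dip /
#'   tail shape whose fitted maximum must be an interior stationary point,
#'   which lower degrees do not reliably deliver.
#' @param epsilon_frac pre-equilibrium band, see [recovery_segment()].
#' @param output_dir if given, recovery curves (CSV), the estimate (JSON)
#'   and the config echo (JSON) are written there.
#'
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(model = c("ebm", "abm"),
                              scenario = c("saddle", "pitchfork"),
                              values,
                              temperature = 2.12, field = 0,
                              amplitude = NULL, r = 0,
                              direction = c("below", "above"),
                              transient = 100, recovery_length = 400,
                              realizations = 100, sigma = 0.01, dt = 0.1,
                              coupling = NULL, L = 100, L_random = FALSE,
                              record_every = 1, start = NULL, degree = 8,
                              epsilon_frac = 0.05, seed = 1,
                              output_dir = NULL) {
  model <- match.arg(model)
  scenario <- match.arg(scenario)
  direction <- match.arg(direction)
  if (scenario == "pitchfork" && field != 0) {
    abort("the pitchfork scenario requires zero external field.")
  }
  if (scenario == "saddle" && is.null(temperature)) {
    abort("the saddle scenario requires a fixed temperature.")
  }
  if (is.null(amplitude)) {
    amplitude <- if (scenario == "saddle") 1 else if (direction == "below") 1 else 0.01
  }
  if (is.null(start)) {
    start <- if (model == "ebm") {
      if (scenario == "saddle") "lower" else if (direction == "above") "upper" else "lower"
    } else {
      if (scenario == "saddle") "down" else if (direction == "above") "up" else "down"
    }
  }
  structure(
    list(
      model = model, scenario = scenario, values = sort(values),
      temperature = temperature, field = field, amplitude = amplitude,
      r = r, direction = direction, transient = transient,
      recovery_length = recovery_length, realizations = realizations,
      sigma = sigma, dt = dt, coupling = coupling, L = L,
      L_random = L_random, record_every = record_every, start = start,
      degree = degree, epsilon_frac = epsilon_frac, seed = seed,
      output_dir = output_dir
    ),
    class = "experiment_config"
  )
}

#' Run a full transition-prediction experiment
#'
#' Executes the complete pipeline: perturbation-recovery ensembles at each
#' configured parameter value, difference curves, pre-equilibrium segment
#' selection, polynomial fits, and linear zero-line extrapolation of the
#' fitted maxima. Optionally writes all artifacts to `output_dir`.
#'
#' @param config an [experiment_config()].
#'
#' @return A [estimate_bifurcation()] result with the recovery experiment
#'   and fitted slopes attached as attributes `experiment` and `slopes`.
#' @export
run_prediction_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  parameter <- if (config$scenario == "saddle") "H" else "T"
  L_use <- if (config$L_random) sample(c(50L, 100L), 1L) else config$L
  model <- if (config$model == "ebm") {
    meanfield_model(
      temperature = config$temperature, field = config$field,
      sigma = config$sigma, dt = config$dt, coupling = config$coupling,
      start = config$start
    )
  } else {
    lattice_model(
      L = L_use, temperature = config$temperature, field = config$field,
      record_every = config$record_every, start = config$start
    )
  }
  spec <- perturbation_spec(
    parameter = parameter, values = config$values,
    mode = if (config$model == "ebm") "state_set" else "alignment_reset",
    amplitude = config$amplitude, r = config$r,
    transient = config$transient, recovery_length = config$recovery_length,
    realizations = config$realizations, seed = config$seed
  )
  experiment <- run_experiment(model, spec)
  slopes <- purrr::map(
    experiment, fit_recovery_slope,
    epsilon_frac = config$epsilon_frac, degree = config$degree
  )
  approach <- if (config$scenario == "saddle") {
    if (config$model == "ebm") "increasing" else "decreasing"
  } else {
    if (config$direction == "below") "increasing" else "decreasing"
  }
  estimate <- estimate_bifurcation(slopes, approach = approach)
  attr(estimate, "experiment") <- experiment
  attr(estimate, "slopes") <- slopes
  attr(estimate, "config") <- config
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_recovery_curves(
      experiment, file.path(config$output_dir, "recovery_curves.csv")
    )
    write_estimate(estimate, file.path(config$output_dir, "estimate.json"))
    cfg <- config
    cfg$output_dir <- NULL
    jsonlite::write_json(
      unclass(cfg), file.path(config$output_dir, "config.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  estimate
}
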