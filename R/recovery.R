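#' Perturbation experiment specification
#'
#' Defines a perturbation-recovery experiment: at each value of the driven
#' parameter the model is simulated through a transient, its state is then
#' perturbed for a single time step, and the return to equilibrium is
#' recorded and averaged over many realizations.
#'
#' @param parameter name of the driven parameter (`"H"`, `"T"`, or `"a"`
#'   for the saddle-node normal form).
#' @param values parameter values `c_1 < ... < c_k`, `k >= 2`; the method
#'   works with a minimum of two perturbations.
#' @param mode `"state_set"` (equation-based models: the state is set to
#'   `amplitude`) or `"alignment_reset"` (lattice: every spin is redrawn
#'   via [perturb_alignment()] with probability `r`).
#' @param amplitude perturbation amplitude for `"state_set"`.
#' @param r alignment probability for `"alignment_reset"`.
#' @param transient steps simulated before the perturbation (default 100).
#' @param recovery_length steps recorded after the perturbation
#'   (default 400).
#' @param realizations ensemble size per parameter value (default 100).
#' @param seed base seed; each parameter value derives its own stream.
#'
#' @return A list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(parameter = "H", values,
                              mode = c("state_set", "alignment_reset"),
                              amplitude = NULL, r = NULL, transient = 100,
                              recovery_length = 400, realizations = 100,
                              seed = 1) {
  mode <- match.arg(mode)
  if (length(values) < 2) abort("need at least two perturbation values (k >= 2).")
  if (transient < 1) abort("`transient` must be >= 1.")
  if (realizations < 1) abort("`realizations` must be >= 1.")
  if (mode == "state_set" && is.null(amplitude)) {
    abort("`amplitude` is required for mode 'state_set'.")
  }
  if (mode == "alignment_reset") {
    if (is.null(r)) abort("`r` is required for mode 'alignment_reset'.")
    if (r < 0 || r > 1) abort("`r` must lie in [0, 1].")
  }
  structure(
    list(
      parameter = parameter, values = sort(values), mode = mode,
      amplitude = amplitude, r = r, transient = as.integer(transient),
      recovery_length = as.integer(recovery_length),
      realizations = as.integer(realizations), seed = seed
    ),
    class = "perturbation_spec"
  )
}

#' Model handles for perturbation experiments
#'
#' Lightweight descriptions of the system to be perturbed; the driven
#' parameter named in the [perturbation_spec()] is substituted per
#' experiment point, all other parameters stay fixed.
#'
#' `meanfield_model()` sits at a deterministic equilibrium branch
#' (`start = "lower"` is the most negative stable root, `"upper"` the most
#' positive) and is perturbed by setting the state. `lattice_model()`
#' starts fully aligned at `start` and is perturbed by redrawing spin
#' alignment. `normal_form_model()` is the saddle-node normal form
#' \eqn{x_{t+1} = x_t + (a - x_t^2)\,dt + \sigma N}, sitting at
#' \eqn{+\sqrt{a}}.
#'
#' @param temperature,field,sigma,dt,coupling mean-field parameters, see
#'   [meanfield_config()].
#' @param start which equilibrium the system occupies before perturbation.
#' @param L,record_every lattice parameters, see [lattice_config()].
#'
#' @return An object of class `meanfield_model`, `lattice_model` or
#'   `normal_form_model`.
#' @export
meanfield_model <- function(temperature = 2.12, field = 0, sigma = 0.01,
                            dt = 0.1, coupling = NULL,
                            start = c("lower", "upper")) {
  structure(
    list(
      temperature = temperature, field = field, sigma = sigma, dt = dt,
      coupling = if (is.null(coupling)) temperature else coupling,
      start = match.arg(start)
    ),
    class = "meanfield_model"
  )
}

#' @rdname meanfield_model
#' @export
lattice_model <- function(L = 100, temperature = 2.12, field = 0,
                          record_every = 1, start = c("down", "up")) {
  structure(
    list(
      L = as.integer(L), temperature = temperature, field = field,
      record_every = as.integer(record_every), start = match.arg(start)
    ),
    class = "lattice_model"
  )
}

#' @rdname meanfield_model
#' @export
normal_form_model <- function(dt = 0.01, sigma = 0) {
  structure(list(dt = dt, sigma = sigma), class = "normal_form_model")
}

new_recovery_curve <- function(mean, sd, value, y_eq, spec, recovered, dt) {
  out <- tibble::tibble(step = seq_along(mean) - 1L, mean = mean, sd = sd)
  structure(out,
    class = c("recovery_curve", class(out)),
    value = value, y_eq = y_eq, parameter = spec$parameter,
    realizations = spec$realizations, recovered = recovered, dt = dt
  )
}

# shared post-processing: ensemble matrix -> recovery curve with
# non-recovery flagged as a warning, never an error
finish_recovery <- function(rec, value, y_eq, spec, dt) {
  mcurve <- rowMeans(rec)
  scurve <- apply(rec, 1, sd)
  band <- 0.05 * abs(mcurve[1] - y_eq)
  recovered <- any(abs(mcurve - y_eq) <= band)
  if (!recovered) {
    warn(sprintf(
      "ensemble mean did not re-enter the 5%% band around y_eq within %d steps at %s = %g",
      spec$recovery_length, spec$parameter, value
    ))
  }
  new_recovery_curve(mcurve, scurve, value, y_eq, spec, recovered, dt)
}

#' Run one perturbation-recovery ensemble
#'
#' For each of `realizations` seeded runs: simulate `transient` steps at
#' the fixed parameter value, apply the perturbation for one time step,
#' and record `recovery_length` further steps. The equilibrium reference
#' `y_eq` is the ensemble mean over the last 20% of the transient window.
#' An ensemble mean that fails to re-enter the 5% band around `y_eq` is
#' flagged with a warning on the curve (attribute `recovered = FALSE`),
#' not an error, so near-bifurcation sweeps can be explored.
#'
#' @param model a [meanfield_model()], [lattice_model()] or
#'   [normal_form_model()].
#' @param spec a [perturbation_spec()].
#' @param value the driven-parameter value for this ensemble.
#' @param seed RNG seed for this ensemble; defaults to `spec$seed`.
#'
#' @return A `recovery_curve` tibble with columns `step`, `mean`, `sd`
#'   (index 0 is the perturbed state) and attributes `value`, `y_eq`,
#'   `recovered`.
#' @export
run_recovery <- function(model, spec, value, seed = spec$seed) {
  UseMethod("run_recovery")
}

#' @export
run_recovery.meanfield_model <- function(model, spec, value, seed = spec$seed) {
  if (spec$mode != "state_set") {
    abort("mean-field models support only mode 'state_set'.")
  }
  set.seed(seed)
  prm <- list(temperature = model$temperature, field = model$field)
  if (spec$parameter == "H") prm$field <- value else prm$temperature <- value
  coupling <- if (spec$parameter == "T") prm$temperature else model$coupling
  eq <- meanfield_equilibria(prm$temperature, prm$field, coupling = coupling)
  stable <- eq$state[eq$stability == "stable"]
  m0 <- if (model$start == "lower") min(stable) else max(stable)
  tr <- simulate_meanfield_ensemble(
    m0, spec$transient, coupling, prm$field,
    model$dt, model$sigma, spec$realizations
  )
  tail_rows <- seq(floor(0.8 * spec$transient) + 1, spec$transient + 1)
  y_eq <- mean(tr[tail_rows, ])
  rec <- simulate_meanfield_ensemble(
    spec$amplitude, spec$recovery_length, coupling, prm$field,
    model$dt, model$sigma, spec$realizations
  )
  finish_recovery(rec, value, y_eq, spec, model$dt)
}

#' @export
run_recovery.normal_form_model <- function(model, spec, value, seed = spec$seed) {
  if (spec$mode != "state_set") {
    abort("normal-form models support only mode 'state_set'.")
  }
  if (value <= 0) abort("recovery experiments need `a` > 0.")
  set.seed(seed)
  a <- value
  step_nf <- function(x, noise) x + (a - x^2) * model$dt + model$sigma * noise
  R <- spec$realizations
  x <- rep(sqrt(a), R)
  tr <- matrix(NA_real_, spec$transient + 1, R)
  tr[1, ] <- x
  for (t in seq_len(spec$transient)) {
    x <- step_nf(x, if (model$sigma > 0) rnorm(R) else 0)
    tr[t + 1, ] <- x
  }
  tail_rows <- seq(floor(0.8 * spec$transient) + 1, spec$transient + 1)
  y_eq <- mean(tr[tail_rows, ])
  x <- rep(spec$amplitude, R)
  rec <- matrix(NA_real_, spec$recovery_length + 1, R)
  rec[1, ] <- x
  for (t in seq_len(spec$recovery_length)) {
    x <- step_nf(x, if (model$sigma > 0) rnorm(R) else 0)
    rec[t + 1, ] <- x
  }
  if (!all(is.finite(rec))) {
    abort("normal-form ensemble diverged; keep the perturbation inside the basin.")
  }
  finish_recovery(rec, value, y_eq, spec, model$dt)
}

#' @export
run_recovery.lattice_model <- function(model, spec, value, seed = spec$seed) {
  if (spec$mode != "alignment_reset") {
    abort("lattice models support only mode 'alignment_reset'.")
  }
  set.seed(seed)
  prm <- list(temperature = model$temperature, field = model$field)
  if (spec$parameter == "H") prm$field <- value else prm$temperature <- value
  eq_sign <- if (model$start == "down") -1L else 1L
  R <- spec$realizations
  n_rec_tr <- spec$transient %/% model$record_every
  n_rec_rec <- spec$recovery_length %/% model$record_every
  tr_mat <- matrix(NA_real_, n_rec_tr, R)
  rec_mat <- matrix(NA_real_, n_rec_rec + 1, R)
  for (rlz in seq_len(R)) {
    lat <- lattice_uniform(model$L, eq_sign)
    res <- cpp_simulate_lattice(
      lat, rep(prm$temperature, spec$transient),
      rep(prm$field, spec$transient), model$record_every, -1L, -1L
    )
    tr_mat[, rlz] <- res$magnetization
    pert <- perturb_alignment(res$spins, spec$r, eq_sign)
    rec_mat[1, rlz] <- magnetization(pert)
    res2 <- cpp_simulate_lattice(
      pert, rep(prm$temperature, spec$recovery_length),
      rep(prm$field, spec$recovery_length), model$record_every, -1L, -1L
    )
    rec_mat[-1, rlz] <- res2$magnetization
  }
  tail_rows <- seq(max(1, floor(0.8 * n_rec_tr)), n_rec_tr)
  y_eq <- mean(tr_mat[tail_rows, ])
  finish_recovery(rec_mat, value, y_eq, spec, model$record_every)
}

#' Run a full perturbation experiment
#'
#' One [run_recovery()] ensemble per parameter value, with independent
#' seeds derived from the base seed; values are processed in sorted order.
#'
#' @param model a model handle, see [meanfield_model()].
#' @param spec a [perturbation_spec()].
#'
#' @return A list of `recovery_curve` objects, class `recovery_experiment`.
#' @export
run_experiment <- function(model, spec) {
  curves <- purrr::imap(
    spec$values,
    function(v, i) run_recovery(model, spec, v, seed = spec$seed + i)
  )
  structure(curves, class = "recovery_experiment", spec = spec, model = model)
}

#' @export
print.recovery_experiment <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf(
    "<recovery_experiment> %d curves over %s in [%g, %g], R=%d\n",
    length(x), spec$parameter, min(spec$values), max(spec$values),
    spec$realizations
  ))
  flags <- purrr::map_lgl(x, ~ attr(.x, "recovered"))
  if (!all(flags)) {
    cat("  non-recovered curves at:", paste(spec$values[!flags], collapse = ", "), "\n")
  }
  invisible(x)
}
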