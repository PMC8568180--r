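#' Construct a trajectory tibble
#'
#' A trajectory is the common currency of the package: a univariate state
#' series (magnetization) together with the value of the slowly driven
#' parameter at every step. Both simulators return this shape, and the
#' estimator and indicator stages consume it.
#'
#' @param values numeric state series, including the initial state.
#' @param dt time step between consecutive states (1 for lattice sweeps).
#' @param parameter_name name of the driven parameter, e.g. `"H"`, `"T"`
#'   or `"a"`.
#' @param parameter_values scalar or per-state vector of parameter values.
#' @param seed RNG seed used to generate the series, or `NULL`.
#' @param model short label of the generating model.
#'
#' @return A tibble of class `ising_trajectory` with columns `time`, `state`
#'   and `parameter`, carrying `dt`, `parameter_name`, `seed` and `model` as
#'   attributes.
#' @export
new_trajectory <- function(values, dt = 1, parameter_name = "H",
                           parameter_values = NA_real_, seed = NULL,
                           model = "custom") {
  n <- length(values)
  if (length(parameter_values) == 1L) {
    parameter_values <- rep(parameter_values, n)
  }
  if (length(parameter_values) != n) {
    abort("`parameter_values` must be scalar or match `values` in length.")
  }
  out <- tibble::tibble(
    time = (seq_len(n) - 1) * dt,
    state = as.numeric(values),
    parameter = as.numeric(parameter_values)
  )
  structure(out,
    class = c("ising_trajectory", class(out)),
    dt = dt, parameter_name = parameter_name,
    seed = seed, model = model
  )
}

#' @export
print.ising_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ising_trajectory> model=%s parameter=%s n=%d dt=%g\n",
    attr(x, "model"), attr(x, "parameter_name"), nrow(x), attr(x, "dt")
  ))
  NextMethod()
}
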