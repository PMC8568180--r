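#' Read and write trajectories
#'
#' Trajectories are stored as plain CSV with columns `time`, `state`,
#' `parameter`; the generating configuration (dt, parameter name, seed,
#' model) is echoed to a JSON sidecar `<path>.json` and restored on read
#' when present.
#'
#' @param trajectory an `ising_trajectory`.
#' @param path CSV file path.
#'
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns an `ising_trajectory`.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "ising_trajectory"))
  readr::write_csv(
    tibble::as_tibble(trajectory)[, c("time", "state", "parameter")], path
  )
  meta <- list(
    dt = attr(trajectory, "dt"),
    parameter_name = attr(trajectory, "parameter_name"),
    seed = attr(trajectory, "seed"),
    model = attr(trajectory, "model")
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE)
  meta <- list(dt = NULL, parameter_name = "H", seed = NULL, model = "file")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- utils::modifyList(meta, jsonlite::read_json(sidecar))
  }
  dt <- if (is.null(meta$dt)) {
    if (nrow(dat) > 1) dat$time[2] - dat$time[1] else 1
  } else {
    meta$dt
  }
  new_trajectory(dat$state,
    dt = dt, parameter_name = meta$parameter_name,
    parameter_values = dat$parameter, seed = meta$seed, model = meta$model
  )
}

#' Write recovery curves to CSV
#'
#' One row per (curve, step): columns `c`, `step`, `mean`, `sd`.
#'
#' @param experiment a `recovery_experiment` (or list of `recovery_curve`).
#' @param path CSV file path.
#' @export
write_recovery_curves <- function(experiment, path) {
  rows <- purrr::map(experiment, function(cv) {
    tibble::tibble(
      c = attr(cv, "value"), step = cv$step, mean = cv$mean, sd = cv$sd
    )
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' Write a bifurcation estimate to JSON
#'
#' Serialises the per-curve inputs (`c_i`, `m_i`, `t_star_i`, `y_star_i`),
#' the regression line, the extrapolated bifurcation parameter and any
#' attached warnings.
#'
#' @param estimate a `bifurcation_estimate`.
#' @param path JSON file path.
#' @export
write_estimate <- function(estimate, path) {
  stopifnot(inherits(estimate, "bifurcation_estimate"))
  payload <- list(
    inputs = estimate$data,
    slope = estimate$slope,
    intercept = estimate$intercept,
    c_hat = estimate$c_hat,
    r_squared = estimate$r_squared,
    warnings = estimate$warnings
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(path)
}

#' Write equilibrium-curve points to CSV
#'
#' @param curves a tibble with columns `parameter` and `state` (e.g. from
#'   [equilibrium_curves()] or [estimate_equilibrium_curve()]).
#' @param path CSV file path.
#' @export
write_equilibrium_curve <- function(curves, path) {
  readr::write_csv(tibble::as_tibble(curves), path)
  invisible(path)
}

#' Write a lattice snapshot as plain text
#'
#' One row of space-separated +1/-1 per lattice row; readable with
#' [read_lattice_snapshot()].
#'
#' @param lattice spin matrix.
#' @param path file path.
#' @export
write_lattice_snapshot <- function(lattice, path) {
  check_lattice(lattice)
  utils::write.table(lattice, path,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_lattice_snapshot
#' @export
read_lattice_snapshot <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  check_lattice(m)
  m
}
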