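#' Lattice constructors
#'
#' A lattice is an `L x L` integer matrix of spins in \{-1, +1\}. Periodic
#' boundary conditions are a property of the update operations, not of the
#' storage. Indices are 1-based `(row, col)`; the "center patch" of an
#' `L x L` lattice is `(floor(L/2) + 1, floor(L/2) + 1)`.
#'
#' @param L side length (>= 2).
#' @param prob_up probability of +1 for the fair-coin initializer.
#' @param spin +1 or -1 for the uniform initializer.
#'
#' @return An `L x L` integer matrix of -1/+1 spins.
#' @export
lattice_random <- function(L, prob_up = 0.5) {
  if (L < 2) abort("`L` must be >= 2.")
  matrix(ifelse(runif(L * L) < prob_up, 1L, -1L), L, L)
}

#' @rdname lattice_random
#' @export
lattice_uniform <- function(L, spin = 1L) {
  if (L < 2) abort("`L` must be >= 2.")
  if (!spin %in% c(-1L, 1L)) abort("`spin` must be -1 or +1.")
  matrix(as.integer(spin), L, L)
}

check_lattice <- function(lattice) {
  if (!is.matrix(lattice) || nrow(lattice) != ncol(lattice)) {
    abort("a lattice must be a square matrix.")
  }
  if (!all(lattice %in% c(-1L, 1L))) abort("all spins must be -1 or +1.")
  invisible(lattice)
}

#' Sum of the four von Neumann neighbors
#'
#' Orthogonal neighbor spins with periodic wrap-around.
#'
#' @param lattice spin matrix.
#' @param i,j 1-based row and column index.
#'
#' @return Integer in \{-4, -2, 0, 2, 4\}.
#' @export
neighbor_sum <- function(lattice, i, j) {
  L <- nrow(lattice)
  if (i < 1 || i > L || j < 1 || j > L) abort("site index out of range.")
  up <- if (i == 1) L else i - 1
  dn <- if (i == L) 1 else i + 1
  lf <- if (j == 1) L else j - 1
  rt <- if (j == L) 1 else j + 1
  lattice[up, j] + lattice[dn, j] + lattice[i, lf] + lattice[i, rt]
}

#' Energy difference of a spin flip
#'
#' The energy a particle gains by flipping: `2 * S * (NB - H)`, with `S`
#' the particle's spin, `NB` the neighbor sum and `H` the external field.
#' Note the sign convention: with this rule a free spin favors the sign
#' opposite to `H`.
#'
#' @param S spin, -1 or +1.
#' @param NB neighbor sum, in -4..4.
#' @param H external field.
#'
#' @return Numeric energy difference.
#' @export
energy_diff <- function(S, NB, H = 0) {
  2 * S * (NB - H)
}

#' Metropolis flip decision
#'
#' A flip is accepted iff `Ediff <= 0` or `p < exp(-Ediff / T)`. The
#' energy-lowering branch consumes no random number.
#'
#' @param Ediff energy difference of the proposed flip.
#' @param temperature temperature `T` (> 0).
#' @param p uniform variate in \[0, 1).
#'
#' @return Logical.
#' @export
flip_decision <- function(Ediff, temperature, p) {
  if (temperature <= 0) abort("`temperature` must be > 0.")
  Ediff <= 0 | p < exp(-Ediff / temperature)
}

#' Magnetization of a lattice
#'
#' The mean spin over all sites, in \[-1, 1\].
#'
#' @param lattice spin matrix.
#' @return Numeric scalar.
#' @export
magnetization <- function(lattice) {
  mean(lattice)
}

#' One Metropolis sweep
#'
#' Performs exactly `L^2` single-site update attempts, each picking a site
#' uniformly at random, computing [energy_diff()] and applying
#' [flip_decision()]. Uses R's RNG stream.
#'
#' @param lattice spin matrix.
#' @param temperature temperature `T` (> 0).
#' @param field external field `H`.
#'
#' @return The updated lattice (a fresh matrix).
#' @export
metropolis_sweep <- function(lattice, temperature, field = 0) {
  check_lattice(lattice)
  if (temperature <= 0) abort("`temperature` must be > 0.")
  res <- cpp_simulate_lattice(lattice, temperature, field, 1L, -1L, -1L)
  res$spins
}

#' Lattice simulation configuration
#'
#' @param L side length, default 100; `L = "random"` draws it from
#'   \{50, 100\} instead.
#' @param temperature temperature; scalar or per-sweep schedule.
#' @param field external field; scalar or per-sweep schedule (linear ramps
#'   via [ramp_schedule()]).
#' @param sweeps number of full-lattice update passes; inferred from a
#'   schedule if one is given.
#' @param record_every sweeps between recorded magnetization samples.
#' @param init `"random"` (fair coin), `"up"`, `"down"`, or a spin matrix.
#' @param seed RNG seed or `NULL`.
#' @param track_site `NULL`, or `c(i, j)` to record that site's spin at
#'   every recorded step; `"center"` tracks the center patch.
#'
#' @return A list of class `lattice_config`.
#' @export
lattice_config <- function(L = 100, temperature = 2.12, field = 0,
                           sweeps = NULL, record_every = 1,
                           init = c("random", "up", "down"), seed = NULL,
                           track_site = NULL) {
  if (identical(L, "random")) L <- sample(c(50L, 100L), 1L)
  if (is.null(sweeps)) {
    sweeps <- max(length(temperature), length(field))
    if (sweeps == 1L) abort("give `sweeps` or a per-sweep schedule.")
  }
  if (sweeps < 1) abort("`sweeps` must be >= 1.")
  for (len in c(length(temperature), length(field))) {
    if (!len %in% c(1L, sweeps)) {
      abort("schedules must be scalar or of length `sweeps`.")
    }
  }
  if (!is.matrix(init)) init <- match.arg(init)
  if (identical(track_site, "center")) {
    track_site <- c(floor(L / 2) + 1L, floor(L / 2) + 1L)
  }
  structure(
    list(
      L = as.integer(L), temperature = temperature, field = field,
      sweeps = as.integer(sweeps), record_every = as.integer(record_every),
      init = init, seed = seed, track_site = track_site
    ),
    class = "lattice_config"
  )
}

#' Linear parameter ramp
#'
#' Per-sweep schedule for a linearly driven parameter; the parameter is
#' constant within each sweep and updated between sweeps.
#'
#' @param from,to endpoints.
#' @param n number of sweeps.
#' @return Numeric vector of length `n`.
#' @export
ramp_schedule <- function(from, to, n) {
  seq(from, to, length.out = n)
}

init_lattice <- function(cfg) {
  if (is.matrix(cfg$init)) {
    check_lattice(cfg$init)
  } else {
    switch(cfg$init,
      random = lattice_random(cfg$L),
      up = lattice_uniform(cfg$L, 1L),
      down = lattice_uniform(cfg$L, -1L)
    )
  }
}

#' Simulate the 2D lattice Ising model
#'
#' Runs Metropolis dynamics under the configured temperature/field
#' schedules, recording magnetization every `record_every` sweeps.
#'
#' @param cfg a [lattice_config()].
#' @param return_spins also return the final spin matrix.
#'
#' @return An [new_trajectory()] tibble (the initial state is recorded as
#'   time 0). If `track_site` is set, a `site_spin` column is added. With
#'   `return_spins = TRUE`, a list `list(trajectory, spins)`.
#' @export
simulate_lattice <- function(cfg, return_spins = FALSE) {
  stopifnot(inherits(cfg, "lattice_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lat <- init_lattice(cfg)
  Ts <- rep(cfg$temperature, length.out = cfg$sweeps)
  Hs <- rep(cfg$field, length.out = cfg$sweeps)
  if (any(Ts <= 0)) abort("`temperature` must be > 0.")
  tr <- if (is.null(cfg$track_site)) c(-1L, -1L) else as.integer(cfg$track_site)
  res <- cpp_simulate_lattice(lat, Ts, Hs, cfg$record_every, tr[1], tr[2])
  rec <- seq(cfg$record_every, cfg$sweeps, by = cfg$record_every)
  varying <- if (length(cfg$temperature) > 1) "T" else "H"
  pvals <- if (varying == "T") Ts[rec] else Hs[rec]
  p0 <- if (varying == "T") Ts[1] else Hs[1]
  traj <- new_trajectory(
    c(magnetization(lat), res$magnetization),
    dt = cfg$record_every, parameter_name = varying,
    parameter_values = c(p0, pvals), seed = cfg$seed, model = "lattice"
  )
  if (!is.null(cfg$track_site)) {
    traj$site_spin <- c(lat[tr[1], tr[2]], res$site_spin)
  }
  if (return_spins) list(trajectory = traj, spins = res$spins) else traj
}

#' Hysteresis loop of the lattice model
#'
#' Ramps the field linearly up and then back down at fixed temperature and
#' returns both magnetization traces. Below the critical temperature the
#' two traces flip at different field values (hysteresis); far above it
#' they coincide within noise.
#'
#' @param temperature fixed temperature.
#' @param L lattice side.
#' @param field_from,field_to ramp endpoints (the up leg runs from
#'   `field_from` to `field_to`; the down leg reverses it).
#' @param sweeps_per_leg sweeps per ramp direction.
#' @param record_every sweeps between samples.
#' @param init initializer for the up leg; the down leg continues from the
#'   final up-leg lattice.
#' @param seed RNG seed.
#'
#' @return A tibble with columns `direction` (`"up"`/`"down"`), `time`,
#'   `state`, `parameter`; class `hysteresis_loop`.
#' @export
hysteresis_loop <- function(temperature = 2.12, L = 50, field_from = -0.5,
                            field_to = 0.6, sweeps_per_leg = 1100,
                            record_every = 1, init = "random", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  up_cfg <- lattice_config(
    L = L, temperature = temperature,
    field = ramp_schedule(field_from, field_to, sweeps_per_leg),
    record_every = record_every, init = init
  )
  up <- simulate_lattice(up_cfg, return_spins = TRUE)
  dn_cfg <- lattice_config(
    L = L, temperature = temperature,
    field = ramp_schedule(field_to, field_from, sweeps_per_leg),
    record_every = record_every, init = up$spins
  )
  dn <- simulate_lattice(dn_cfg)
  out <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(up$trajectory), direction = "up"),
    dplyr::mutate(tibble::as_tibble(dn), direction = "down")
  )[, c("direction", "time", "state", "parameter")]
  structure(out,
    class = c("hysteresis_loop", class(out)),
    temperature = temperature, L = L, seed = seed
  )
}

#' Transition fields of a hysteresis loop
#'
#' Locates, for each ramp direction, the field at which the (smoothed)
#' magnetization first crosses zero. The smoothing window suppresses
#' single-sweep noise; transitions are reported as `NA` when no crossing
#' occurs.
#'
#' @param loop a [hysteresis_loop()] result.
#' @param smooth odd moving-average window (samples).
#'
#' @return Named numeric vector `c(up = ..., down = ...)`.
#' @export
transition_fields <- function(loop, smooth = 51) {
  smooth_ma <- function(x) {
    as.numeric(stats::filter(x, rep(1 / smooth, smooth), sides = 2))
  }
  one <- function(d) {
    m <- smooth_ma(d$state)
    s0 <- sign(m[!is.na(m)][1])
    i <- which(!is.na(m) & sign(m) == -s0)[1]
    if (is.na(i)) NA_real_ else d$parameter[i]
  }
  updat <- loop[loop$direction == "up", ]
  dndat <- loop[loop$direction == "down", ]
  c(up = one(updat), down = one(dndat))
}

#' Empirical site-state probability across an ensemble
#'
#' Fraction of realizations in which a tracked site is in the given spin
#' state, per recorded step.
#'
#' @param trajectories a list of trajectories produced by
#'   [simulate_lattice()] with `track_site` set (>= 2 realizations).
#' @param state spin state of interest, -1 or +1.
#'
#' @return A tibble with columns `time` and `probability`; class
#'   `site_probability_trace`.
#' @export
site_state_probability <- function(trajectories, state = -1L) {
  if (length(trajectories) < 2) abort("need at least 2 realizations.")
  if (!all(purrr::map_lgl(trajectories, ~ "site_spin" %in% names(.x)))) {
    abort("trajectories must carry a `site_spin` column (use `track_site`).")
  }
  spins <- do.call(cbind, purrr::map(trajectories, "site_spin"))
  out <- tibble::tibble(
    time = trajectories[[1]]$time,
    probability = rowMeans(spins == state)
  )
  structure(out, class = c("site_probability_trace", class(out)), state = state)
}

#' Perturb a lattice by resetting alignment probabilities
#'
#' Every spin is independently reset to `equilibrium_sign` with probability
#' `r` and to the opposite sign with probability `1 - r`. `r = 1` restores
#' full alignment with the reference equilibrium; `r = 0` flips the lattice
#' to the opposite extreme; `r = 0.5` produces an unordered lattice.
#'
#' @param lattice spin matrix.
#' @param r alignment probability in \[0, 1\].
#' @param equilibrium_sign reference equilibrium sign, -1 or +1.
#'
#' @return The perturbed lattice.
#' @export
perturb_alignment <- function(lattice, r, equilibrium_sign) {
  check_lattice(lattice)
  if (r < 0 || r > 1) abort("`r` must lie in [0, 1].")
  if (!equilibrium_sign %in% c(-1L, 1L)) abort("`equilibrium_sign` must be -1 or +1.")
  L <- nrow(lattice)
  matrix(ifelse(runif(L * L) < r, as.integer(equilibrium_sign),
    -as.integer(equilibrium_sign)
  ), L, L)
}

#' @importFrom purrr map_lgl
NULL
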