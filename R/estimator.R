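#' First-order discrete differences of a recovery curve
#'
#' @param recovery a `recovery_curve` or a numeric state series.
#'
#' @return Numeric vector `d(t) = y(t+1) - y(t)`, one element shorter than
#'   the input.
#' @export
difference_curve <- function(recovery) {
  y <- if (inherits(recovery, "recovery_curve")) recovery$mean else as.numeric(recovery)
  if (length(y) < 2) abort("recovery curve must have at least 2 points.")
  diff(y)
}

#' Pre-equilibrium segment of a recovery curve
#'
#' The part of the recovery on which the system has not yet returned to
#' equilibrium: time indices `t` (0-based, `t = 0` is the perturbed state)
#' before the first `t` with
#' `|y(t) - y_eq| <= epsilon_frac * |y(0) - y_eq|`. If the band is never
#' reached the whole curve is returned.
#'
#' @param recovery a `recovery_curve`, or a numeric series (then `y_eq`
#'   must be given).
#' @param epsilon_frac band half-width as a fraction of the initial
#'   displacement, default 0.05.
#' @param y_eq equilibrium reference; taken from the curve's attribute by
#'   default.
#'
#' @return Integer vector of 0-based time indices (possibly empty).
#' @export
recovery_segment <- function(recovery, epsilon_frac = 0.05, y_eq = NULL) {
  y <- if (inherits(recovery, "recovery_curve")) recovery$mean else as.numeric(recovery)
  if (is.null(y_eq)) y_eq <- attr(recovery, "y_eq")
  if (is.null(y_eq)) abort("`y_eq` is required for plain numeric input.")
  band <- epsilon_frac * abs(y[1] - y_eq)
  hit <- which(abs(y - y_eq) <= band)
  t_end <- if (length(hit)) hit[1] - 1L else length(y)  # 0-based exclusive end
  seq_len(t_end) - 1L
}

#' Least-squares polynomial fit of a difference curve
#'
#' Fits a polynomial of the given degree to the difference curve over the
#' pre-equilibrium segment (internally on a \[0, 1\]-scaled axis for
#' numerical conditioning) and locates the maximum of the fitted polynomial
#' on a dense 1000-point grid over the segment.
#'
#' @param differences numeric difference curve, `d(t)` for `t = 0, 1, ...`.
#' @param segment 0-based time indices to fit over (see
#'   [recovery_segment()]); indices beyond the difference curve are
#'   dropped.
#' @param degree polynomial degree, 2-8 (default 4).
#' @param values optional state series `y(t)` used to report the state at
#'   the fitted maximum.
#' @param value driven-parameter value this curve belongs to.
#'
#' @return An object of class `fitted_slope`: a list with the fitted
#'   maximum `m`, its position `t_star`, the state `y_star` (if `values`
#'   given), the coefficients and the segment.
#' @export
fit_slope <- function(differences, segment, degree = 4, values = NULL,
                      value = NA_real_) {
  if (!degree %in% 2:8) abort("`degree` must be an integer in 2..8.")
  segment <- segment[segment <= length(differences) - 1L]
  if (length(segment) <= degree) {
    abort("insufficient recovery segment: need more points than the degree.")
  }
  d <- differences[segment + 1L]
  t0 <- min(segment)
  t1 <- max(segment)
  s <- if (t1 > t0) (segment - t0) / (t1 - t0) else rep(0, length(segment))
  X <- outer(s, 0:degree, `^`)
  beta <- qr.coef(qr(X), d)
  beta[is.na(beta)] <- 0
  s_grid <- seq(0, 1, length.out = 1000)
  fitted <- drop(outer(s_grid, 0:degree, `^`) %*% beta)
  i_max <- which.max(fitted)
  t_star <- t0 + s_grid[i_max] * (t1 - t0)
  y_star <- if (!is.null(values)) {
    stats::approx(seq_along(values) - 1L, values, xout = t_star)$y
  } else {
    NA_real_
  }
  structure(
    list(
      value = value, differences = differences, segment = segment,
      coefficients = unname(beta), degree = degree, t_star = unname(t_star),
      m = unname(fitted[i_max]), y_star = y_star, t_range = c(t0, t1),
      values = values
    ),
    class = "fitted_slope"
  )
}

#' Difference curve, segment and polynomial fit of one recovery curve
#'
#' Convenience wrapper chaining [difference_curve()],
#' [recovery_segment()] and [fit_slope()] for a `recovery_curve`.
#'
#' @param recovery a `recovery_curve`.
#' @inheritParams fit_slope
#' @inheritParams recovery_segment
#'
#' @return A `fitted_slope`.
#' @export
fit_recovery_slope <- function(recovery, epsilon_frac = 0.05, degree = 4) {
  stopifnot(inherits(recovery, "recovery_curve"))
  fit_slope(
    difference_curve(recovery),
    recovery_segment(recovery, epsilon_frac),
    degree = degree, values = recovery$mean, value = attr(recovery, "value")
  )
}

# evaluate a fitted_slope polynomial at 0-based time positions
eval_slope <- function(slope, t) {
  t0 <- slope$t_range[1]
  t1 <- slope$t_range[2]
  s <- if (t1 > t0) (t - t0) / (t1 - t0) else rep(0, length(t))
  drop(outer(s, 0:slope$degree, `^`) %*% slope$coefficients)
}

#' Estimate the bifurcation point by zero-line extrapolation
#'
#' Fits an ordinary least-squares line to the fitted difference-curve
#' maxima `m_i` against the parameter values `c_i` at which the system was
#' perturbed, and extends it to the zero line. The zero crossing
#' `c_hat = -intercept / slope` is the parameter value at which recovery
#' would cease: the estimated bifurcation point. Two perturbations are
#' sufficient (the line then passes through both points exactly).
#'
#' @param x a data frame with columns `c` and `m`, or a list of
#'   `fitted_slope` objects (e.g. from mapping [fit_recovery_slope()] over
#'   a [run_experiment()] result).
#' @param approach direction in which the perturbation values approach the
#'   transition: `"increasing"`, `"decreasing"`, or `"unknown"` (default).
#'   When known, a fitted line whose slope implies recovery speeding up
#'   toward the transition is flagged with a warning; an extrapolation
#'   landing between the perturbation values is allowed.
#'
#' @return An object of class `bifurcation_estimate` with elements
#'   `data` (per-curve tibble), `slope`, `intercept`, `c_hat`,
#'   `r_squared` and `warnings`. [tidy()] and [glance()] methods apply.
#' @export
#'
#' @examples
#' estimate_bifurcation(data.frame(c = c(-0.2, -0.12), m = c(-0.05, -0.02)))
estimate_bifurcation <- function(x, approach = c("unknown", "increasing", "decreasing")) {
  approach <- match.arg(approach)
  if (is.list(x) && all(purrr::map_lgl(x, inherits, "fitted_slope"))) {
    x <- tibble::tibble(
      c = purrr::map_dbl(x, "value"),
      m = purrr::map_dbl(x, "m"),
      t_star = purrr::map_dbl(x, "t_star"),
      y_star = purrr::map_dbl(x, "y_star")
    )
  }
  x <- tibble::as_tibble(x)
  if (!all(c("c", "m") %in% names(x))) abort("`x` needs columns `c` and `m`.")
  if (length(unique(x$c)) < 2) abort("need at least 2 distinct parameter values.")
  fit <- lm(m ~ c, data = x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  # treat numerically-zero slopes (all m equal up to rounding) as degenerate
  scale <- (abs(mean(x$m)) + abs(intercept) + 1e-300) / diff(range(x$c))
  if (!is.finite(slope) || abs(slope) < 1e-10 * scale) {
    abort("zero slope: cannot extrapolate to the zero line.")
  }
  c_hat <- -intercept / slope
  r2 <- if (nrow(x) > 2) summary(fit)$r.squared else 1
  warnings <- character(0)
  # recovery must slow toward the transition: |m| shrinking along the
  # approach direction; the opposite pattern still extrapolates but is
  # flagged (requires a known approach direction and single-signed m)
  if (approach != "unknown" && (all(x$m < 0) || all(x$m > 0))) {
    # |m| must shrink toward the crossing: for negative m and an upward
    # approach the line must rise, etc.
    expected <- -sign(mean(x$m)) * (if (approach == "increasing") 1 else -1)
    if (sign(slope) != expected) {
      warnings <- c(
        warnings, "slope sign implies recovery speeds up toward the transition"
      )
    }
  }
  if (length(warnings)) warn(warnings[1])
  structure(
    list(
      data = x, slope = slope, intercept = intercept, c_hat = c_hat,
      r_squared = r2, warnings = warnings
    ),
    class = "bifurcation_estimate"
  )
}

#' @export
print.bifurcation_estimate <- function(x, ...) {
  cat("<bifurcation_estimate>\n")
  cat(sprintf(
    "  c_hat = %.6g  (slope %.4g, intercept %.4g, R^2 %.4f, k = %d)\n",
    x$c_hat, x$slope, x$intercept, x$r_squared, nrow(x$data)
  ))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
tidy.bifurcation_estimate <- function(x, ...) {
  x$data
}

#' @export
glance.bifurcation_estimate <- function(x, ...) {
  tibble::tibble(
    c_hat = x$c_hat, slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, n = nrow(x$data),
    warnings = paste(x$warnings, collapse = "; ")
  )
}

#' Approximate the equilibrium curve near the bifurcation
#'
#' A correlated sample of points is read off the fitted difference curves:
#' at each relative position `q` along each curve's segment the fitted
#' difference and the state are taken, the differences are regressed on
#' the parameter at fixed `q` and extrapolated to the zero line, and the
#' resulting parameter value is paired with the mean state at `q`. The
#' collection over `q` traces the estimated equilibrium curve.
#'
#' @param slopes list of `fitted_slope` objects (>= 2) carrying state
#'   series (`fit_recovery_slope()` provides them).
#' @param q relative positions along the segments, default `0.1 ... 0.9`.
#'
#' @return A tibble with columns `q`, `parameter`, `state`; at most
#'   `length(q)` rows. Degenerate `q` levels (zero slope) are dropped;
#'   fewer than 2 usable levels is an error.
#' @export
estimate_equilibrium_curve <- function(slopes, q = seq(0.1, 0.9, by = 0.1)) {
  if (length(slopes) < 2) abort("need at least 2 fitted slopes.")
  cs <- purrr::map_dbl(slopes, "value")
  rows <- purrr::map(q, function(qi) {
    d_q <- purrr::map_dbl(slopes, function(s) {
      t_q <- s$t_range[1] + qi * diff(s$t_range)
      eval_slope(s, t_q)
    })
    y_q <- purrr::map_dbl(slopes, function(s) {
      t_q <- s$t_range[1] + qi * diff(s$t_range)
      if (is.null(s$values)) return(NA_real_)
      stats::approx(seq_along(s$values) - 1L, s$values, xout = t_q)$y
    })
    fit <- lm(d_q ~ cs)
    sl <- unname(coef(fit)[2])
    if (!is.finite(sl) || abs(sl) < 1e-12) {
      return(NULL)
    }
    tibble::tibble(
      q = qi, parameter = -unname(coef(fit)[1]) / sl, state = mean(y_q)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) < 2) abort("zero slope at every q: cannot trace the equilibrium curve.")
  out <- out[is.finite(out$parameter) & is.finite(out$state), ]
  structure(out, class = c("equilibrium_curve_estimate", class(out)))
}
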