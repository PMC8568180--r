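#' Classical early-warning-signal indicators
#'
#' Scalar indicators computed on a univariate series: lag-1 Pearson
#' autocorrelation (`ews_ar1`), population standard deviation (`ews_std`),
#' third and fourth standardized moments (`ews_skewness`, `ews_kurtosis`;
#' kurtosis uses the Pearson convention where a Gaussian scores 3),
#' the detrended-fluctuation-analysis exponent ([dfa_exponent()]) and the
#' spectral reddening ratio ([spectral_reddening()]). As a system
#' approaches a critical transition, critical slowing down raises AR1,
#' variance and reddening.
#'
#' @param x numeric series.
#' @name ews_indicators
NULL

#' @rdname ews_indicators
#' @export
ews_ar1 <- function(x) {
  n <- length(x)
  if (n < 3) abort("need at least 3 points for AR1.")
  if (sd(x) == 0) abort("constant series: AR1 undefined.")
  unname(cor(x[-n], x[-1]))
}

#' @rdname ews_indicators
#' @export
ews_std <- function(x) {
  if (length(x) < 4) abort("need at least 4 points.")
  sqrt(mean((x - mean(x))^2))
}

#' @rdname ews_indicators
#' @export
ews_skewness <- function(x) {
  if (length(x) < 4) abort("need at least 4 points.")
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) abort("constant series: skewness undefined.")
  mean((x - mean(x))^3) / m2^1.5
}

#' @rdname ews_indicators
#' @export
ews_kurtosis <- function(x) {
  if (length(x) < 4) abort("need at least 4 points.")
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) abort("constant series: kurtosis undefined.")
  mean((x - mean(x))^4) / m2^2
}

#' Detrended fluctuation analysis exponent
#'
#' DFA of order 1: the series is cumulated around its mean, split into
#' non-overlapping boxes of logarithmically spaced sizes in
#' \[10, n/4\], a linear trend is removed within each box, and the scaling
#' exponent is the slope of the log-log regression of RMS fluctuation
#' against box size. White noise scores about 0.5, its cumulative sum
#' about 1.5.
#'
#' @param x numeric series (length >= 100).
#' @param n_scales number of box sizes.
#'
#' @return The DFA exponent (numeric scalar).
#' @export
dfa_exponent <- function(x, n_scales = 16) {
  n <- length(x)
  if (n < 100) abort("need at least 100 points for DFA.")
  profile <- cumsum(x - mean(x))
  scales <- unique(round(exp(seq(log(10), log(n / 4), length.out = n_scales))))
  flucts <- purrr::map_dbl(scales, function(s) {
    n_box <- n %/% s
    idx <- seq_len(n_box * s)
    boxes <- matrix(profile[idx], nrow = s)
    t <- seq_len(s)
    resid2 <- apply(boxes, 2, function(y) {
      fit <- .lm.fit(cbind(1, t), y)
      mean(fit$residuals^2)
    })
    sqrt(mean(resid2))
  })
  unname(coef(lm(log(flucts) ~ log(scales)))[2])
}

#' Spectral reddening ratio
#'
#' The ratio of mean periodogram power over the lowest 20% of nonzero
#' frequencies to mean power over the highest 20%. White noise scores
#' about 1; series dominated by slow fluctuations (as near a transition)
#' score well above 1.
#'
#' @param x numeric series (length >= 64).
#' @param band fraction of the nonzero frequencies in each band.
#'
#' @return The low/high power ratio (numeric scalar).
#' @export
spectral_reddening <- function(x, band = 0.2) {
  n <- length(x)
  if (n < 64) abort("need at least 64 points for the spectral ratio.")
  p <- Mod(fft(x - mean(x)))^2
  nf <- n %/% 2
  power <- p[2:(nf + 1)]  # nonzero frequencies
  k <- max(1L, floor(band * nf))
  low <- mean(power[seq_len(k)])
  high <- mean(power[seq.int(nf - k + 1L, nf)])
  if (high == 0) abort("zero high-band power: ratio undefined.")
  low / high
}

#' @importFrom stats .lm.fit
NULL

#' Rolling-window EWS trace
#'
#' Evaluates the six indicators on rolling windows over a series. The
#' windows can traverse time within one realization, or — when the series
#' is a parameter sweep — traverse the swept parameter; in both cases the
#' input is the univariate state series and the optional parameter column
#' is carried through to label the windows.
#'
#' Windows with zero variance are flagged in the `degenerate` column; on
#' them AR1, skewness and kurtosis are `NA` while the standard deviation
#' is 0.
#'
#' @param data a trajectory tibble (columns `state`, optionally
#'   `parameter`) or a numeric series.
#' @param window window length in samples (default 250, half of the
#'   500-step series the indicator comparison typically uses).
#' @param step advance between windows (default 10).
#' @param detrend remove the within-window mean before computing the
#'   indicators (default TRUE). The moment-based indicators are
#'   translation invariant; detrending matters for DFA and the
#'   periodogram only through the mean removal already applied there.
#'
#' @return An `ews_trace` tibble: one row per window with columns
#'   `window`, `end` (sample index of the window end), `parameter` (value
#'   at the window end, if available), `ar1`, `std`, `skewness`,
#'   `kurtosis`, `dfa`, `fr`, `degenerate`.
#' @export
rolling_ews <- function(data, window = 250, step = 10, detrend = TRUE) {
  if (is.data.frame(data)) {
    x <- data$state
    par <- if ("parameter" %in% names(data)) data$parameter else rep(NA_real_, length(x))
  } else {
    x <- as.numeric(data)
    par <- rep(NA_real_, length(x))
  }
  n <- length(x)
  if (window > n || window < 4) abort("invalid window length.")
  starts <- seq(1L, n - window + 1L, by = step)
  rows <- purrr::imap(starts, function(s0, i) {
    end_idx <- s0 + window - 1L
    w <- x[s0:end_idx]
    if (detrend) w <- w - mean(w)
    degenerate <- sd(w) == 0
    vals <- list(
      ar1 = if (degenerate) NA_real_ else ews_ar1(w),
      std = ews_std(w),
      skewness = if (degenerate) NA_real_ else ews_skewness(w),
      kurtosis = if (degenerate) NA_real_ else ews_kurtosis(w),
      dfa = if (degenerate || window < 100) NA_real_ else dfa_exponent(w),
      fr = if (degenerate || window < 64) NA_real_ else spectral_reddening(w)
    )
    tibble::tibble(
      window = i, end = end_idx, parameter = par[end_idx],
      !!!vals, degenerate = degenerate
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
    class = c("ews_trace", class(out)),
    window = window, step = step, detrend = detrend
  )
}
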