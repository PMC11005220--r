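# Circadian rhythm estimation: least-squares periodogram over a period grid
# and cosinor (harmonic regression) rhythm parameters.
#
# The estimand matches autoregressive-spectral rhythm tooling (period,
# amplitude, adjusted phase, rhythm-adjusted mean/base) but is computed in
# closed form by ordinary least squares on a 1-min period grid, which
# resolves periods that do not sit on the Fourier grid of a 72-h window
# (the ~23.7-h murine cycle among them).

#' Remove a least-squares linear trend from a series
#'
#' @param series numeric vector (length >= 3); interior missing values are
#'   linearly interpolated before fitting.
#' @param interval_min sampling step in minutes.
#' @return residuals of the OLS line fit on time; zero vector for constant
#'   input.
#' @export
detrend_linear <- function(series, interval_min = 18) {
  y <- interp_gaps(as.numeric(series))
  n <- length(y)
  if (n < 3) stop("detrend_linear needs at least 3 samples")
  t <- (seq_len(n) - 1) * interval_min
  tc <- t - mean(t)
  stt <- sum(tc^2)
  slope <- if (stt > 0) sum(tc * (y - mean(y))) / stt else 0
  y - mean(y) - slope * tc
}

# Partial R^2 of the (cos, sin) pair at each candidate period, given the
# baseline regressors (intercept, optionally a linear trend).
.harmonic_power <- function(y, t, periods, trend = FALSE) {
  base <- if (trend) cbind(1, t) else matrix(1, length(y), 1)
  qb <- qr(base)
  r0 <- qr.resid(qb, y)
  rss0 <- sum(r0^2)
  if (rss0 <= 0) return(rep(0, length(periods)))
  vapply(periods, function(tau) {
    w <- 2 * pi / tau
    X <- cbind(base, cos(w * t), sin(w * t))
    rss <- sum(qr.resid(qr(X), y)^2)
    min(max(1 - rss / rss0, 0), 1)
  }, numeric(1))
}

# Indices of strict local maxima of `x`; plateaus count once, at their
# leftmost index, and grid endpoints are not maxima.
.local_maxima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  i <- 2:(k - 1)
  hit <- i[r$values[i] > r$values[i - 1] & r$values[i] > r$values[i + 1]]
  sort(starts[hit])
}

#' Least-squares periodogram and top-k circadian periods
#'
#' For every candidate period on a minute-resolution grid, computes the
#' fraction of series variance explained by a cosine/sine pair at that
#' period (fit jointly with an intercept, and optionally a linear trend so
#' that a slow drift cannot masquerade as rhythm power or bias the peak).
#' The top-k periods are the local maxima of this power curve, ranked by
#' power; ties break toward the shorter period.
#'
#' @param series numeric vector; interior gaps are linearly interpolated.
#' @param interval_min sampling step in minutes.
#' @param grid `(min_period, max_period, step)` in minutes, default
#'   `c(1200, 1680, 1)` (20-28 h).
#' @param k number of top periods to return (default 5).
#' @param trend if `TRUE`, include a linear time trend in the baseline fit.
#' @return list with `periodogram` (class `ee_periodogram`: `period_grid_min`,
#'   `power`) and `top_periods` (numeric, length <= k; attribute
#'   `incomplete = TRUE` plus a warning when fewer than `k` local maxima
#'   exist).
#' @export
periodogram_top_periods <- function(series, interval_min = 18,
                                    grid = c(1200, 1680, 1), k = 5,
                                    trend = FALSE) {
  y <- interp_gaps(as.numeric(series))
  n <- length(y)
  span <- n * interval_min
  if (span < 2 * grid[2])
    stop(sprintf(
      "coverage error: window (%g min) must span at least two cycles of the longest candidate period (%g min)",
      span, grid[2]))
  periods <- seq(grid[1], grid[2], by = grid[3])
  t <- (seq_len(n) - 1) * interval_min
  power <- .harmonic_power(y, t, periods, trend = trend)
  pg <- structure(list(period_grid_min = periods, power = power),
                  class = "ee_periodogram")
  im <- .local_maxima(power)
  # rank by power descending; ties toward the shorter period
  im <- im[order(-power[im], periods[im])]
  top <- periods[utils::head(im, k)]
  if (length(top) < k) {
    warning(sprintf("only %d local maxima found (k = %d requested)",
                    length(top), k))
    attr(top, "incomplete") <- TRUE
  }
  list(periodogram = pg, top_periods = top)
}

#' @export
print.ee_periodogram <- function(x, ...) {
  imax <- which.max(x$power)
  cat(sprintf(
    "<ee_periodogram> %d candidate periods in [%g, %g] min; peak %.3f at %g min\n",
    length(x$period_grid_min), min(x$period_grid_min),
    max(x$period_grid_min), x$power[imax], x$period_grid_min[imax]))
  invisible(x)
}

#' Cosinor fit of a single-component circadian rhythm
#'
#' Ordinary least squares of `y ~ 1 + cos(2*pi*t/tau) + sin(2*pi*t/tau)`.
#' The intercept is the MESOR (rhythm-adjusted mean, the "base" value),
#' the amplitude is `sqrt(beta_cos^2 + beta_sin^2)` (half peak-to-trough),
#' and the adjusted phase is the fitted peak time expressed in minutes
#' after lights-on, wrapped to `[0, tau)`.
#'
#' @param series numeric vector (length >= 4); interior gaps interpolated.
#' @param interval_min sampling step in minutes.
#' @param period_min fitted period tau in minutes.
#' @param t0_min phase reference: minutes elapsed from lights-on to the
#'   first sample (0 if the series starts at lights-on). For a
#'   `cage_recording`, use [cosinor_fit_recording()] which fills this in.
#' @return object of class `rhythm_params`: `period_min`, `amplitude`,
#'   `adjphase_min`, `mesor`, `rsq`, plus fit internals.
#' @export
cosinor_fit <- function(series, interval_min = 18, period_min = 1423,
                        t0_min = 0) {
  y <- interp_gaps(as.numeric(series))
  n <- length(y)
  if (n < 4) stop("cosinor_fit needs at least 4 samples")
  if (n * interval_min < 2 * period_min)
    stop("coverage error: window must contain at least two full periods")
  t_abs <- t0_min + (seq_len(n) - 1) * interval_min
  w <- 2 * pi / period_min
  X <- cbind(1, cos(w * t_abs), sin(w * t_abs))
  qx <- qr(X)
  if (qx$rank < 3)
    stop("conditioning error: singular cosinor design at this period")
  beta <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  tss <- sum((y - mean(y))^2)
  rsq <- if (tss > 0) min(max(1 - sum(res^2) / tss, 0), 1) else 0
  amp <- sqrt(beta[2]^2 + beta[3]^2)
  if (tss == 0 || amp < .Machine$double.eps * max(1, abs(beta[1]))) {
    amp <- 0
    adj <- 0
  } else {
    # peak where cos(w t - phi) is maximal: t = phi / w, phi = atan2(bs, bc)
    adj <- (atan2(beta[3], beta[2]) / w) %% period_min
  }
  structure(list(period_min = period_min, amplitude = unname(amp),
                 adjphase_min = unname(adj), mesor = unname(beta[1]),
                 rsq = rsq, coef = unname(beta), n = n),
            class = "rhythm_params")
}

#' @export
print.rhythm_params <- function(x, ...) {
  cat(sprintf(
    "<rhythm_params> tau=%g min  mesor=%.4g  amplitude=%.4g  adjphase=%.1f min  R2=%.3f\n",
    x$period_min, x$mesor, x$amplitude, x$adjphase_min, x$rsq))
  invisible(x)
}

#' Cosinor fit of a recording channel, phase-referenced to lights-on
#'
#' Applies [cosinor_fit()] to one channel of a recording, with the phase
#' reference taken from the recording's light schedule, and enforces the
#' gap policy (channels with more than `max_gap_frac` missing samples are
#' rejected; smaller interior gaps are linearly interpolated for the fit).
#'
#' @param rec a `cage_recording`.
#' @param channel channel name, default `"EE"`.
#' @param period_min fitted period in minutes (default 1423, the common
#'   optimal circadian cycle of murine energy expenditure).
#' @param max_gap_frac maximum tolerated fraction of missing samples
#'   (default 0.05).
#' @return a `rhythm_params` object.
#' @export
cosinor_fit_recording <- function(rec, channel = "EE", period_min = 1423,
                                  max_gap_frac = 0.05) {
  y <- rec$channels[[channel]]
  if (is.null(y)) stop(sprintf("channel %s absent from recording", channel))
  if (gap_fraction(y) > max_gap_frac)
    stop(sprintf("channel %s has %.1f%% missing samples (> %g%% tolerated)",
                 channel, 100 * gap_fraction(y), 100 * max_gap_frac))
  cosinor_fit(y, rec$interval_min, period_min,
              t0_min = minutes_after_lights_on(rec))
}
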