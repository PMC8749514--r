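## Heart-rate-variability features.
##
## Eight features per window: five time-domain indices computed from the raw
## RR intervals falling in the window (meanNN, SDNN, RMSSD, total power,
## NN50) and three frequency-domain indices (LF, HF, LF/HF) computed from
## the 1 s-resampled RRI trace restricted to the window via a Yule-Walker
## autoregressive spectrum.

HRV_FEATURE_NAMES <- c("meanNN", "SDNN", "RMSSD", "total_power", "NN50",
                       "LF", "HF", "LF_HF")

#' Time-domain HRV features of one window
#'
#' @param intervals RR intervals in ms inside one window (at least 2).
#' @return Named numeric vector: \code{meanNN} (ms), \code{SDNN} (ms,
#'   population SD), \code{RMSSD} (ms), \code{total_power} (ms^2, defined as
#'   the population variance of the in-window intervals, i.e. SDNN^2) and
#'   \code{NN50} (count of successive differences strictly greater than
#'   50 ms).
#' @examples
#' hrv_time_features(c(800, 860, 870))
#' @export
hrv_time_features <- function(intervals) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 2)
    stop("insufficient data: need at least 2 RR intervals in the window")
  m <- mean(intervals)
  v <- mean((intervals - m)^2)          # population variance
  d <- diff(intervals)
  c(meanNN = m,
    SDNN = sqrt(v),
    RMSSD = sqrt(mean(d^2)),
    total_power = v,
    NN50 = sum(abs(d) > 50))            # strictly > 50 ms
}

#' Autoregressive power spectral density (Yule-Walker)
#'
#' Estimates the PSD of a uniformly sampled signal from an AR model fitted by
#' the Yule-Walker equations (via \code{stats::ar.yw}). The signal is
#' mean-removed before fitting. The one-sided density is
#' \deqn{S(f) = 2 \sigma^2 \Delta / |1 - \sum_k a_k e^{-2\pi i f k \Delta}|^2}
#' with \eqn{\Delta} the sampling interval and \eqn{\sigma^2} the innovation
#' variance, so that the integral of \code{densities} over \code{[0,
#' Nyquist]} approximates the process variance (in ms^2 for RRI input).
#'
#' @param x Numeric vector or scalar \code{\link{uniform_series}}.
#' @param order AR model order (default 10). Requires \code{length(x) > order}.
#' @param n_freq Number of grid points over \code{[0, Nyquist]} (default 512).
#' @param interval Sampling interval in seconds; taken from the series when
#'   \code{x} is a \code{uniform_series}.
#' @return Object of class \code{ar_psd}: list with \code{frequencies} (Hz),
#'   \code{densities} (ms^2/Hz, nonnegative) and \code{model_order}.
#' @export
ar_psd <- function(x, order = 10, n_freq = 512, interval = 1) {
  if (inherits(x, "uniform_series")) {
    if (ncol(x$values) != 1) stop("ar_psd expects a single-channel series")
    interval <- 1 / x$rate
    x <- as.numeric(x$values)
  }
  x <- as.numeric(x)
  if (anyNA(x)) stop("ar_psd: input contains missing values")
  if (length(x) <= order)
    stop(sprintf("insufficient data: need more than %d samples for AR(%d)",
                 order, order))
  freqs <- seq(0, 0.5 / interval, length.out = n_freq)
  x <- x - mean(x)
  if (all(x == 0)) {
    dens <- rep(0, n_freq)
  } else {
    fit <- ar.yw(x, aic = FALSE, order.max = order, demean = TRUE)
    a <- fit$ar
    sig2 <- fit$var.pred
    ## transfer denominator |1 - sum a_k z^-k|^2 on the grid
    if (length(a)) {
      ek <- exp(-2i * pi * outer(freqs * interval, seq_along(a)))
      A <- 1 - as.vector(ek %*% a)
    } else A <- rep(1 + 0i, n_freq)
    dens <- 2 * sig2 * interval / Mod(A)^2
  }
  structure(list(frequencies = freqs, densities = dens, model_order = order),
            class = "ar_psd")
}

#' @export
print.ar_psd <- function(x, ...) {
  cat(sprintf("ar_psd: AR(%d) spectrum, %d points over [0, %g] Hz, total power %.3g\n",
              x$model_order, length(x$frequencies), max(x$frequencies),
              band_power(x, 0, max(x$frequencies))))
  invisible(x)
}

#' @export
plot.ar_psd <- function(x, ...) {
  plot(x$frequencies, x$densities, type = "l",
       xlab = "frequency [Hz]", ylab = "PSD [ms²/Hz]", ...)
  invisible(x)
}

#' Integrated spectral power in a frequency band
#'
#' Trapezoidal integral of an \code{\link{ar_psd}} over \code{[lo, hi]}, with
#' linear interpolation at the band edges. Used for the LF (0.04--0.15 Hz)
#' and HF (0.15--0.4 Hz) heart-rate-variability bands.
#'
#' @param psd An \code{ar_psd}.
#' @param lo,hi Band edges in Hz, \code{0 <= lo < hi <= Nyquist}.
#' @return Band power (ms^2).
#' @export
band_power <- function(psd, lo, hi) {
  stopifnot(inherits(psd, "ar_psd"))
  fmax <- max(psd$frequencies)
  if (!is.finite(lo) || !is.finite(hi) || lo < 0 || hi > fmax + 1e-12 || lo >= hi)
    stop(sprintf("invalid band [%g, %g]: need 0 <= lo < hi <= %g", lo, hi, fmax))
  f <- psd$frequencies
  d <- psd$densities
  edge <- function(ff) approx(f, d, xout = ff, rule = 2)$y
  inside <- f > lo & f < hi
  ff <- c(lo, f[inside], hi)
  dd <- c(edge(lo), d[inside], edge(hi))
  sum(diff(ff) * (head(dd, -1) + tail(dd, -1)) / 2)
}

#' HRV feature vector of one window
#'
#' Computes the eight-element HRV feature vector for the window ending at
#' \code{end_time}: time-domain indices from the raw in-window intervals and
#' LF/HF band powers from the resampled trace restricted to the window.
#'
#' @param rri An \code{\link{rri_series}}.
#' @param end_time Window end time (seconds).
#' @param window Window length in seconds (default 120).
#' @param resampled Optional precomputed \code{\link{resample_rri}} output
#'   (computed on the fly if omitted).
#' @param ar_order Yule-Walker AR order for the spectrum (default 10).
#' @param lf_band,hf_band Frequency bands in Hz.
#' @return Named numeric vector of length 8 in the fixed order
#'   \code{meanNN, SDNN, RMSSD, total_power, NN50, LF, HF, LF_HF}.
#'   \code{LF_HF} is \code{NA} when HF is zero.
#' @export
hrv_window_features <- function(rri, end_time, window = 120, resampled = NULL,
                                ar_order = 10, lf_band = c(0.04, 0.15),
                                hf_band = c(0.15, 0.40)) {
  pay <- window_payload(rri, end_time, window)
  iv <- pay$intervals[pay$valid]
  if (length(iv) < 4)
    stop("insufficient data: window covers fewer than 4 valid beats")
  td <- hrv_time_features(iv)
  if (is.null(resampled)) resampled <- resample_rri(rri)
  xw <- window_payload(resampled, end_time, window)
  if (nrow(xw) <= ar_order)
    stop("insufficient resampled samples in window for the AR fit")
  psd <- ar_psd(as.numeric(xw), order = ar_order, interval = 1 / resampled$rate)
  lf <- band_power(psd, lf_band[1], lf_band[2])
  hf <- band_power(psd, hf_band[1], hf_band[2])
  c(td, LF = lf, HF = hf, LF_HF = if (hf > 0) lf / hf else NA_real_)
}

#' Sliding-window HRV feature extraction
#'
#' Slides a window (default 120 s, 1 s slide) over an RR-interval series and
#' computes the eight HRV features per window. Windows in which the fraction
#' of flagged (implausible or gap) intervals exceeds \code{max_missing}, or
#' with too few beats for the calculation, are kept in the output with
#' \code{NA} features so that downstream detection can propagate MISSING
#' rather than silently skipping time.
#'
#' @inheritParams hrv_window_features
#' @param window,slide Window length and slide interval in seconds.
#' @param max_missing Maximum tolerated in-window missing fraction
#'   (default 0.3).
#' @return Data frame with column \code{t_end} followed by the 8 features.
#' @examples
#' rri <- rri_series(cumsum(rep(0.8, 400)), rep(800, 400))
#' feats <- extract_hrv_features(rri, window = 120, slide = 10)
#' names(feats)
#' @export
extract_hrv_features <- function(rri, window = 120, slide = 1, ar_order = 10,
                                 lf_band = c(0.04, 0.15),
                                 hf_band = c(0.15, 0.40), max_missing = 0.3) {
  stopifnot(inherits(rri, "rri_series"))
  ends <- slide_windows(rri, window, slide)
  out <- matrix(NA_real_, length(ends), 8,
                dimnames = list(NULL, HRV_FEATURE_NAMES))
  if (!length(ends))
    return(cbind(data.frame(t_end = numeric(0)), as.data.frame(out)))
  resampled <- resample_rri(rri)
  rs_times <- sample_times(resampled)
  rs_vals <- as.numeric(resampled$values)
  bt <- rri$beat_times
  for (k in seq_along(ends)) {
    te <- ends[k]
    sel <- bt >= te - window & bt < te
    if (!any(sel)) next
    mf <- mean(!rri$valid[sel])
    iv <- rri$intervals[sel][rri$valid[sel]]
    if (mf > max_missing || length(iv) < 4) next
    td <- hrv_time_features(iv)
    xs <- rs_vals[rs_times >= te - window & rs_times < te]
    if (length(xs) <= ar_order) next
    psd <- ar_psd(xs, order = ar_order, interval = 1 / resampled$rate)
    lf <- band_power(psd, lf_band[1], lf_band[2])
    hf <- band_power(psd, hf_band[1], hf_band[2])
    out[k, ] <- c(td, lf, hf, if (hf > 0) lf / hf else NA_real_)
  }
  cbind(data.frame(t_end = ends), as.data.frame(out))
}
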