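#' Regularly sampled signal
#'
#' Container for a uniformly sampled scalar or multi-channel signal, such as
#' tri-axial wrist acceleration at 100 Hz or a 1 Hz resampled RR-interval
#' trace. Sample \code{k} (1-based) is located at time
#' \code{start_time + (k - 1) / rate} seconds.
#'
#' @param values Numeric vector (single channel) or matrix with one column
#'   per channel. All values must be finite or \code{NA} (explicitly missing).
#' @param rate Sampling rate in Hz; must be positive.
#' @param start_time Time of the first sample in seconds.
#' @param channel_names Optional character vector of channel identifiers.
#' @return An object of class \code{uniform_series} with fields
#'   \code{values} (matrix), \code{rate}, \code{start_time},
#'   \code{channel_names}.
#' @examples
#' s <- uniform_series(sin(2 * pi * 2 * (0:99) / 100), rate = 100)
#' duration(s)
#' @export
uniform_series <- function(values, rate, start_time = 0, channel_names = NULL) {
  if (!is.matrix(values)) values <- matrix(as.numeric(values), ncol = 1)
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a single positive number (Hz)")
  if (ncol(values) < 1) stop("at least one channel is required")
  if (any(is.infinite(values)))
    stop("signal values must be finite or NA")
  if (is.null(channel_names)) {
    channel_names <- colnames(values)
    if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(values)))
  }
  if (length(channel_names) != ncol(values))
    stop("length of 'channel_names' must match the number of channels")
  colnames(values) <- channel_names
  structure(
    list(values = values, rate = as.numeric(rate),
         start_time = as.numeric(start_time), channel_names = channel_names),
    class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("uniform_series: %d samples x %d channel(s) @ %g Hz, t = [%g, %g) s\n",
              nrow(x$values), ncol(x$values), x$rate, x$start_time,
              x$start_time + nrow(x$values) / x$rate))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Signal duration in seconds
#'
#' @param x A \code{uniform_series} or \code{rri_series}.
#' @return Duration in seconds. For an \code{rri_series} this is the span
#'   from the first to the last beat time.
#' @export
duration <- function(x) UseMethod("duration")

#' @export
duration.uniform_series <- function(x) nrow(x$values) / x$rate

#' @export
duration.rri_series <- function(x) {
  if (length(x$beat_times) < 2) return(0)
  max(x$beat_times) - min(x$beat_times)
}

#' Sample times of a uniform series
#' @param x A \code{uniform_series}.
#' @return Numeric vector of sample times in seconds.
#' @export
sample_times <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  x$start_time + (seq_len(nrow(x$values)) - 1) / x$rate
}

#' RR-interval event series
#'
#' Irregular series of RR intervals (beat-to-beat times from the ECG R wave),
#' the raw input to heart-rate-variability analysis. Each element pairs the
#' time of a detected beat with the RR interval that ends at that beat.
#'
#' Intervals are screened on construction: values outside the physiological
#' plausibility band, or much longer than the series' typical interval
#' (gaps left by undetected beats, which merge two or more true intervals),
#' are flagged invalid. \code{missing_fraction} is the flagged proportion and
#' is always computed, never supplied.
#'
#' @param beat_times Strictly increasing beat times in seconds.
#' @param intervals RR intervals in ms, one per beat time, each > 0.
#' @param plausibility Two-element band (ms); intervals outside are flagged
#'   missing. Default 300--2000 ms.
#' @param gap_factor Intervals longer than \code{gap_factor} times the median
#'   in-band interval are flagged missing (dropped-beat gaps). Default 1.75.
#' @return An object of class \code{rri_series} with fields
#'   \code{beat_times}, \code{intervals}, \code{valid} (logical),
#'   \code{missing_fraction}.
#' @examples
#' rri <- rri_series(beat_times = cumsum(rep(0.8, 50)),
#'                   intervals = rep(800, 50))
#' rri$missing_fraction
#' @export
rri_series <- function(beat_times, intervals,
                       plausibility = c(300, 2000), gap_factor = 1.75) {
  beat_times <- as.numeric(beat_times)
  intervals <- as.numeric(intervals)
  if (length(beat_times) != length(intervals))
    stop("'beat_times' and 'intervals' must have equal length")
  if (length(beat_times) && any(diff(beat_times) <= 0))
    stop("'beat_times' must be strictly increasing")
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("all RR intervals must be finite and > 0 ms")
  in_band <- intervals >= plausibility[1] & intervals <= plausibility[2]
  valid <- in_band
  if (any(in_band)) {
    med <- median(intervals[in_band])
    valid <- in_band & intervals <= gap_factor * med
  }
  structure(
    list(beat_times = beat_times, intervals = intervals, valid = valid,
         missing_fraction = if (length(valid)) mean(!valid) else 0),
    class = "rri_series")
}

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf("rri_series: %d beats over %.1f s, mean RR %.1f ms, missing fraction %.3f\n",
              length(x$beat_times), duration(x),
              mean(x$intervals[x$valid]), x$missing_fraction))
  invisible(x)
}

## ---- CSV readers/writers -------------------------------------------------

## Timestamps may be float seconds or ISO-8601; auto-detected.
parse_time_column <- function(tm, path) {
  if (is.numeric(tm)) return(as.numeric(tm))
  tt <- suppressWarnings(as.numeric(tm))
  if (!anyNA(tt)) return(tt)
  pt <- suppressWarnings(as.POSIXct(tm, tz = "UTC",
                                    tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                                   "%Y-%m-%d %H:%M:%OS")))
  if (anyNA(pt)) {
    bad <- which(is.na(pt))[1]
    stop(sprintf("%s: unparseable timestamp at data line %d: '%s'",
                 path, bad, tm[bad]))
  }
  as.numeric(pt) - as.numeric(pt[1])
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop(path, ": empty input file")
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop(path, ": malformed CSV: ",
                                          conditionMessage(e)))
  if (nrow(df) == 0) stop(path, ": no data rows")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read / write RR-interval CSV files
#'
#' The file format has a header row with columns \code{time_s} (beat time,
#' float seconds or ISO-8601, auto-detected) and \code{rri_ms}. Malformed
#' rows raise an error naming the offending data line.
#'
#' @param path Path to a CSV file.
#' @param ... Passed to \code{\link{rri_series}} (plausibility band, gap rule).
#' @return \code{read_rri_csv} returns an \code{\link{rri_series}}.
#' @export
read_rri_csv <- function(path, ...) {
  df <- read_checked_csv(path, c("time_s", "rri_ms"))
  tm <- parse_time_column(df$time_s, path)
  iv <- suppressWarnings(as.numeric(df$rri_ms))
  if (anyNA(iv))
    stop(sprintf("%s: non-numeric rri_ms at data line %d", path, which(is.na(iv))[1]))
  bad <- which(!is.finite(iv) | iv <= 0)
  if (length(bad))
    stop(sprintf("%s: non-positive RR interval at data line %d", path, bad[1]))
  if (any(diff(tm) <= 0)) {
    bad <- which(diff(tm) <= 0)[1] + 1
    stop(sprintf("%s: beat times not strictly increasing at data line %d", path, bad))
  }
  rri_series(tm, iv, ...)
}

#' @rdname read_rri_csv
#' @param x An \code{rri_series}.
#' @export
write_rri_csv <- function(x, path) {
  stopifnot(inherits(x, "rri_series"))
  write.csv(data.frame(time_s = x$beat_times, rri_ms = x$intervals),
            path, row.names = FALSE)
  invisible(path)
}

#' Read / write tri-axial accelerometer CSV files
#'
#' Expected columns: \code{time_s, ax_g, ay_g, az_g}, one file per sensor
#' (e.g. left wrist, right wrist). The sampling rate is inferred from the
#' time column and checked for uniformity.
#'
#' @param path Path to a CSV file.
#' @param units Units of the acceleration columns: \code{"g"} (default) or
#'   \code{"ms2"}, in which case values are converted to g.
#' @param sensor Optional sensor identifier prefixed to channel names.
#' @return \code{read_accel_csv} returns a 3-channel
#'   \code{\link{uniform_series}} with channels x, y, z in g.
#' @export
read_accel_csv <- function(path, units = c("g", "ms2"), sensor = NULL) {
  units <- match.arg(units)
  df <- read_checked_csv(path, c("time_s", "ax_g", "ay_g", "az_g"))
  tm <- parse_time_column(df$time_s, path)
  vals <- as.matrix(df[, c("ax_g", "ay_g", "az_g")])
  storage.mode(vals) <- "double"
  if (any(is.infinite(vals)))
    stop(path, ": non-finite acceleration value")
  if (units == "ms2") vals <- vals / 9.80665
  if (nrow(vals) < 2) stop(path, ": need at least 2 samples")
  dt <- diff(tm)
  if (any(dt <= 0)) stop(path, ": time column not strictly increasing")
  step <- median(dt)
  if (max(abs(dt - step)) > 0.01 * step)
    stop(path, ": sampling is not uniform")
  ch <- c("x", "y", "z")
  if (!is.null(sensor)) ch <- paste(sensor, ch, sep = "_")
  uniform_series(vals, rate = 1 / step, start_time = tm[1], channel_names = ch)
}

#' @rdname read_accel_csv
#' @param x A 3-channel \code{uniform_series} in g.
#' @export
write_accel_csv <- function(x, path) {
  stopifnot(inherits(x, "uniform_series"), ncol(x$values) == 3)
  write.csv(data.frame(time_s = sample_times(x),
                       ax_g = x$values[, 1], ay_g = x$values[, 2],
                       az_g = x$values[, 3]),
            path, row.names = FALSE)
  invisible(path)
}

## ---- Preprocessing -------------------------------------------------------

#' Zero-phase Butterworth low-pass filter
#'
#' Removes high-frequency noise from accelerometer channels with a
#' Butterworth low-pass filter applied forward and backward
#' (\code{signal::filtfilt}), so the output is not time-shifted relative to
#' annotations. The default (3rd order, 12.5 Hz cut-off) matches standard
#' wearable-IMU preprocessing at a 100 Hz sampling rate. Because of the
#' two-pass application the effective magnitude response is the squared
#' one-pass Butterworth response; DC gain remains exactly 1.
#'
#' @param series A \code{\link{uniform_series}}.
#' @param cutoff Cut-off frequency in Hz; must be below the Nyquist
#'   frequency \code{series$rate / 2}.
#' @param order Filter order (one pass). Default 3.
#' @return A filtered \code{uniform_series} with identical shape and rate.
#' @export
lowpass_accel <- function(series, cutoff = 12.5, order = 3) {
  stopifnot(inherits(series, "uniform_series"))
  nyq <- series$rate / 2
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= nyq)
    stop(sprintf("cutoff must lie in (0, %g) Hz (Nyquist); got %g", nyq, cutoff))
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  out <- series
  for (j in seq_len(ncol(series$values)))
    out$values[, j] <- zero_phase_filter(bf, series$values[, j])
  out
}

## Forward-backward filtering with odd-reflection padding at both ends so
## that startup transients die out inside the pad (exact DC gain).
zero_phase_filter <- function(bf, x) {
  n <- length(x)
  L <- min(n - 1, 300)
  xx <- c(2 * x[1] - x[(L + 1):2], x, 2 * x[n] - x[(n - 1):(n - L)])
  y <- as.numeric(signal::filter(bf, xx))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(L + 1):(L + n)]
}

#' Resample an RR-interval series onto a uniform grid
#'
#' Interpolates the irregular RR-interval series with a cubic spline and
#' resamples it at a fixed interval (default 1 s), as required for
#' autoregressive spectral analysis. Only intervals that passed the
#' plausibility/gap screen are used as spline knots, so flagged gaps are
#' bridged smoothly.
#'
#' @param rri An \code{\link{rri_series}}.
#' @param interval Resampling interval in seconds (default 1).
#' @return A scalar \code{\link{uniform_series}} (channel \code{"rri_ms"}) at
#'   \code{1/interval} Hz spanning the valid beats.
#' @export
resample_rri <- function(rri, interval = 1) {
  stopifnot(inherits(rri, "rri_series"))
  keep <- rri$valid
  if (sum(keep) < 4)
    stop("insufficient data: cubic-spline resampling needs at least 4 valid beats")
  tx <- rri$beat_times[keep]
  ty <- rri$intervals[keep]
  xout <- seq(tx[1], tx[length(tx)], by = interval)
  yi <- spline(tx, ty, xout = xout, method = "fmm")$y
  uniform_series(yi, rate = 1 / interval, start_time = xout[1],
                 channel_names = "rri_ms")
}

## ---- Sliding windows -----------------------------------------------------

#' Sliding-window end times
#'
#' Windows of length \code{W} seconds are slid over the signal at a fixed
#' \code{slide} interval. A window is the half-open span
#' \code{[end - W, end)} and is labeled by its END time, so any quantity
#' computed from it uses only past data. For a signal of duration D the
#' number of windows is \code{floor((D - W)/slide) + 1}; a signal shorter
#' than \code{W} yields no windows (with a message, not an error).
#'
#' @param x A \code{uniform_series} or \code{rri_series}.
#' @param W Window length in seconds.
#' @param slide Slide interval in seconds (default 1).
#' @return Numeric vector of window end times (possibly empty).
#' @examples
#' s <- uniform_series(rnorm(300), rate = 1)
#' length(slide_windows(s, W = 120, slide = 1))  # 181
#' @export
slide_windows <- function(x, W, slide = 1) {
  stopifnot(W > 0, slide > 0)
  t0 <- if (inherits(x, "rri_series")) {
    if (length(x$beat_times) == 0) return(numeric(0)) else min(x$beat_times)
  } else x$start_time
  D <- duration(x)
  if (D < W) {
    message(sprintf("signal duration %.3f s < window %.3f s: no windows", D, W))
    return(numeric(0))
  }
  n <- floor((D - W) / slide + 1e-9) + 1
  t0 + W + (seq_len(n) - 1) * slide
}

#' Extract one window's payload
#'
#' Returns the samples (or beats) covered by the half-open window
#' \code{[end_time - W, end_time)}.
#'
#' @param x A \code{uniform_series} or \code{rri_series}.
#' @param end_time Window end time in seconds.
#' @param W Window length in seconds.
#' @return For a \code{uniform_series}, a matrix of samples; for an
#'   \code{rri_series}, a list with \code{intervals}, \code{valid} and
#'   \code{missing_fraction} restricted to the window.
#' @export
window_payload <- function(x, end_time, W) UseMethod("window_payload")

#' @export
window_payload.uniform_series <- function(x, end_time, W) {
  a <- end_time - W
  i1 <- ceiling((a - x$start_time) * x$rate + 1 - 1e-9)
  i2 <- ceiling((end_time - x$start_time) * x$rate + 1 - 1e-9) - 1
  i1 <- max(i1, 1); i2 <- min(i2, nrow(x$values))
  if (i2 < i1) return(x$values[0, , drop = FALSE])
  x$values[i1:i2, , drop = FALSE]
}

#' @export
window_payload.rri_series <- function(x, end_time, W) {
  sel <- x$beat_times >= end_time - W & x$beat_times < end_time
  list(intervals = x$intervals[sel], valid = x$valid[sel],
       missing_fraction = if (any(sel)) mean(!x$valid[sel]) else NA_real_)
}
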