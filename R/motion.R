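## Wrist-motion features.
##
## The inattention detector uses sub-window-difference features: each window
## is split into Nsw equal sub-windows, the mean acceleration of each
## sub-window is taken, adjacent sub-window means are differenced, and the
## variance/skewness/kurtosis of the difference distribution summarise how
## much fine-grained steering micro-correction is present. The body-movement
## detector uses plain per-channel mean and variance, the standard
## human-activity-recognition pair.

#' Sub-window mean amplitudes
#'
#' Splits a window of samples into \code{nsw} contiguous sub-windows of
#' (maximally) equal size and returns the arithmetic mean of each. When the
#' sample count is not divisible by \code{nsw}, boundaries are placed by
#' rounding cumulative fractional indices, so sub-window sizes differ by at
#' most one sample.
#'
#' @param x Numeric vector of samples from one axis (length >= \code{nsw}).
#' @param nsw Number of sub-windows (default 60).
#' @return Numeric vector of \code{nsw} sub-window means.
#' @export
subwindow_amplitudes <- function(x, nsw = 60) {
  x <- as.numeric(x)
  n <- length(x)
  if (nsw < 1) stop("'nsw' must be >= 1")
  if (n < nsw)
    stop(sprintf("insufficient data: %d samples for %d sub-windows", n, nsw))
  b <- round(seq_len(nsw) * n / nsw)
  cs <- c(0, cumsum(x))
  lo <- c(0, b[-nsw])
  (cs[b + 1] - cs[lo + 1]) / (b - lo)
}

#' Adjacent sub-window differences
#'
#' First differences of the sub-window mean amplitudes,
#' \code{d[i] = A[i+1] - A[i]}. The differences telescope:
#' \code{sum(d) == A[nsw] - A[1]}.
#'
#' @param A Numeric vector of sub-window amplitudes (length >= 2).
#' @return Numeric vector of length \code{length(A) - 1}.
#' @export
diff_sequence <- function(A) {
  if (length(A) < 2) stop("need at least 2 sub-windows to difference")
  diff(A)
}

#' Distribution-shape statistics of a difference sequence
#'
#' Population (1/n) moment statistics of the sub-window difference
#' distribution: variance, skewness (third standardised moment) and excess
#' kurtosis (normal distribution gives 0). A zero-spread sequence is
#' degenerate: variance is 0 and skewness/kurtosis are imputed as 0 so that
#' downstream multivariate monitoring receives finite values.
#'
#' @param d Numeric vector of differences (length >= 3 for meaningful shape
#'   statistics).
#' @return Named numeric vector \code{c(variance, skewness, kurtosis)}.
#' @export
motion_stats <- function(d) {
  d <- as.numeric(d)
  if (length(d) < 1) stop("empty difference sequence")
  m <- mean(d)
  m2 <- mean((d - m)^2)
  ## degenerate guard: a spread below 1e-10 g is far under any sensor
  ## resolution (and covers float residue from cumulative-sum paths)
  if (m2 <= 1e-20)
    return(c(variance = 0, skewness = 0, kurtosis = 0))
  m3 <- mean((d - m)^3)
  m4 <- mean((d - m)^4)
  c(variance = m2, skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

motion_channel_names <- function(sensors = c("L", "R"), axes = c("x", "y", "z"),
                                 stats = c("var", "skew", "kurt")) {
  as.vector(t(outer(as.vector(t(outer(sensors, axes, paste, sep = "_"))),
                    stats, paste, sep = "_")))
}

MOTION_FEATURE_NAMES <- motion_channel_names()

#' Motion features of one window pair
#'
#' Computes the 18-element motion feature vector for one window: for each of
#' the two wrists and each of the three axes, the variance, skewness and
#' kurtosis of the adjacent sub-window mean differences. Ordering is fixed
#' and serialised with fitted models: left (x, y, z) then right (x, y, z),
#' each as (variance, skewness, kurtosis).
#'
#' @param left,right Matrices (samples x 3 axes) covering one window, e.g.
#'   from \code{\link{window_payload}}.
#' @param nsw Number of sub-windows (default 60).
#' @return Named numeric vector of length 18.
#' @export
motion_window_features <- function(left, right, nsw = 60) {
  stopifnot(is.matrix(left), is.matrix(right),
            ncol(left) == 3, ncol(right) == 3)
  vals <- unlist(lapply(list(left, right), function(m)
    lapply(1:3, function(j)
      motion_stats(diff_sequence(subwindow_amplitudes(m[, j], nsw))))))
  names(vals) <- MOTION_FEATURE_NAMES
  vals
}

#' Body-movement (HAR) features of one window pair
#'
#' Per-channel mean and population variance of acceleration, the classic
#' human-activity-recognition summary used to flag large body movements such
#' as repositioning a hand on the wheel.
#'
#' @param left,right Matrices (samples x 3 axes) covering one window.
#' @return Named numeric vector of length 12:
#'   \code{L_x_mean, L_x_var, ..., R_z_var}.
#' @export
bodymove_window_features <- function(left, right) {
  stopifnot(is.matrix(left), is.matrix(right), nrow(left) > 0, nrow(right) > 0)
  vals <- unlist(lapply(list(left, right), function(m)
    lapply(1:3, function(j)
      c(mean(m[, j]), mean((m[, j] - mean(m[, j]))^2)))))
  names(vals) <- motion_channel_names(stats = c("mean", "var"))
  vals
}

intersect_ends <- function(a, b) {
  if (!length(a) || !length(b)) return(numeric(0))
  a[round(a * 1e6) %in% round(b * 1e6)]
}

## Window sample-index bounds identical to window_payload.uniform_series.
window_index_bounds <- function(series, ends, W) {
  i1 <- ceiling((ends - W - series$start_time) * series$rate + 1 - 1e-9)
  i2 <- ceiling((ends - series$start_time) * series$rate + 1 - 1e-9) - 1
  cbind(pmax(i1, 1), pmin(i2, nrow(series$values)))
}

## Shared sliding-window driver over the two wrist series. `fun` maps
## (left window matrix, right window matrix) -> named numeric vector.
slide_accel_features <- function(left, right, window, slide, fun, nms) {
  stopifnot(inherits(left, "uniform_series"), inherits(right, "uniform_series"),
            ncol(left$values) == 3, ncol(right$values) == 3)
  ends <- intersect_ends(slide_windows(left, window, slide),
                         slide_windows(right, window, slide))
  out <- matrix(NA_real_, length(ends), length(nms),
                dimnames = list(NULL, nms))
  bl <- window_index_bounds(left, ends, window)
  br <- window_index_bounds(right, ends, window)
  for (k in seq_along(ends)) {
    lw <- left$values[bl[k, 1]:bl[k, 2], , drop = FALSE]
    rw <- right$values[br[k, 1]:br[k, 2], , drop = FALSE]
    v <- tryCatch(fun(lw, rw), error = function(e) rep(NA_real_, length(nms)))
    out[k, ] <- v
  }
  cbind(data.frame(t_end = ends), as.data.frame(out))
}

#' Sliding-window motion feature extraction
#'
#' Slides a window (default 60 s, 1 s slide) jointly over the two wrist
#' accelerometer series and computes the 18 sub-window-difference motion
#' features per window.
#'
#' @param left,right 3-channel \code{\link{uniform_series}} for the left and
#'   right wrist (ideally low-pass filtered first; see
#'   \code{\link{lowpass_accel}}).
#' @param window,slide Window length and slide interval in seconds.
#' @param nsw Number of sub-windows per window (default 60).
#' @return Data frame with column \code{t_end} followed by the 18 features
#'   \code{L_x_var, L_x_skew, L_x_kurt, ..., R_z_kurt}.
#' @export
extract_motion_features <- function(left, right, window = 60, slide = 1,
                                    nsw = 60) {
  stopifnot(inherits(left, "uniform_series"), inherits(right, "uniform_series"),
            ncol(left$values) == 3, ncol(right$values) == 3)
  ends <- intersect_ends(slide_windows(left, window, slide),
                         slide_windows(right, window, slide))
  out <- matrix(NA_real_, length(ends), 18,
                dimnames = list(NULL, MOTION_FEATURE_NAMES))
  if (!length(ends))
    return(cbind(data.frame(t_end = ends), as.data.frame(out)))
  bounds <- list(window_index_bounds(left, ends, window),
                 window_index_bounds(right, ends, window))
  ## per-channel global cumulative sums: each sub-window mean is then an
  ## O(1) difference, matching subwindow_amplitudes() exactly
  cs <- c(lapply(1:3, function(j) c(0, cumsum(left$values[, j]))),
          lapply(1:3, function(j) c(0, cumsum(right$values[, j]))))
  for (k in seq_along(ends)) {
    col <- 0
    for (ch in 1:6) {
      b <- bounds[[(ch - 1) %/% 3 + 1]]
      n <- b[k, 2] - b[k, 1] + 1
      if (n < nsw) { col <- col + 3; next }
      bb <- round(seq_len(nsw) * n / nsw)
      cuts <- cs[[ch]][b[k, 1] + c(0, bb) - 1 + 1]
      A <- diff(cuts) / diff(c(0, bb))
      out[k, col + 1:3] <- motion_stats(diff(A))
      col <- col + 3
    }
  }
  cbind(data.frame(t_end = ends), as.data.frame(out))
}

#' Sliding-window body-movement feature extraction
#'
#' Slides a short window (default 2 s, 1 s slide) over the two wrist series
#' and computes per-channel mean and variance.
#'
#' @inheritParams extract_motion_features
#' @return Data frame with column \code{t_end} followed by 12 features.
#' @export
extract_bodymove_features <- function(left, right, window = 2, slide = 1) {
  slide_accel_features(left, right, window, slide, bodymove_window_features,
                       motion_channel_names(stats = c("mean", "var")))
}
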