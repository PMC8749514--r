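## Decision flow, annotation labeling and evaluation.
##
## Three per-state anomaly detectors (body movement, drowsiness,
## inattention) each vote "anomaly" or not for every slide interval; a
## fixed-priority flow turns the three votes into one driver state. The
## flow is causal and sequential: body movement is checked first and is
## terminal; only if no body movement is found does the drowsiness model
## decide, then the inattention model; if none fires the state is normal.

DRIVER_STATES <- c("BODY_MOVEMENT", "DROWSINESS", "INATTENTION", "NORMAL",
                   "MISSING")

#' Fuse per-stage anomaly votes into a driver state
#'
#' Priority decision flow: BODY_MOVEMENT > DROWSINESS > INATTENTION >
#' NORMAL. Stages are consulted in that order and the first enabled stage
#' voting anomaly determines the state. An enabled stage whose vote is
#' missing (\code{NA}) makes the state MISSING: the flow cannot pass a stage
#' it cannot evaluate. Disabled stages are skipped entirely.
#'
#' @param bm,drw,atv Logical vectors (recycled to a common length) of
#'   anomaly votes from the body-movement, drowsiness and inattention
#'   models; \code{NA} = vote unavailable.
#' @param stages Named logical vector enabling each stage. The default
#'   enables all three; the feasibility configuration evaluated in practice
#'   disables \code{body_movement}.
#' @return Factor with levels \code{BODY_MOVEMENT, DROWSINESS, INATTENTION,
#'   NORMAL, MISSING}.
#' @examples
#' fuse_states(TRUE, TRUE, TRUE)    # BODY_MOVEMENT
#' fuse_states(FALSE, FALSE, FALSE) # NORMAL
#' fuse_states(FALSE, TRUE, FALSE)  # DROWSINESS
#' @export
fuse_states <- function(bm, drw, atv,
                        stages = c(body_movement = TRUE, drowsiness = TRUE,
                                   inattention = TRUE)) {
  n <- max(length(bm), length(drw), length(atv))
  bm <- rep_len(as.logical(bm), n)
  drw <- rep_len(as.logical(drw), n)
  atv <- rep_len(as.logical(atv), n)
  votes <- list(BODY_MOVEMENT = bm, DROWSINESS = drw, INATTENTION = atv)
  enabled <- c(isTRUE(stages[["body_movement"]]),
               isTRUE(stages[["drowsiness"]]),
               isTRUE(stages[["inattention"]]))
  out <- rep("NORMAL", n)
  undecided <- rep(TRUE, n)
  for (k in 1:3) {
    if (!enabled[k]) next
    v <- votes[[k]]
    hit_na <- undecided & is.na(v)
    out[hit_na] <- "MISSING"
    undecided[hit_na] <- FALSE
    hit <- undecided & !is.na(v) & v
    out[hit] <- names(votes)[k]
    undecided[hit] <- FALSE
  }
  factor(out, levels = DRIVER_STATES)
}

## ---- Annotation labeling -------------------------------------------------

#' Label drowsiness from referee scores
#'
#' Converts 5 s-resolution averaged referee drowsiness scores (6-point
#' scale) into a boolean series on the detection grid: an interval whose
#' average score is 2.0 or more (inclusive) is drowsy. Each 5 s score is
#' held over \code{[time, time + step)} when upsampling.
#'
#' @param scores Data frame with \code{time_s} and either a single
#'   \code{score} column (already averaged over referees) or several
#'   \code{score_*} columns, which are averaged row-wise.
#' @param grid_times Numeric vector of detection grid times (seconds).
#' @param threshold Drowsiness threshold on the averaged score (default 2.0,
#'   inclusive).
#' @return Logical vector along \code{grid_times} (\code{NA} outside the
#'   annotated span).
#' @export
label_drowsiness <- function(scores, grid_times, threshold = 2.0) {
  stopifnot(is.data.frame(scores), "time_s" %in% names(scores))
  if ("score" %in% names(scores)) {
    sc <- scores$score
  } else {
    cols <- grep("^score", names(scores), value = TRUE)
    if (!length(cols)) stop("no score column(s) found")
    sc <- rowMeans(scores[, cols, drop = FALSE])
  }
  if (any(sc < 1 - 1e-9 | sc > 6 + 1e-9))
    stop("referee scores must lie in [1, 6]")
  tm <- scores$time_s
  step <- if (length(tm) > 1) median(diff(tm)) else 5
  idx <- findInterval(grid_times, tm)
  lab <- rep(NA, length(grid_times))
  ok <- idx >= 1 & grid_times < tm[length(tm)] + step
  lab[ok] <- sc[idx[ok]] >= threshold
  lab
}

#' Label inattention from vigilance-task reaction times
#'
#' Computes the per-participant reaction-time threshold mean + 1 SD (sample
#' SD, n-1) and labels each RT event inattentive when its RT is at or above
#' the threshold (inclusive). An event at time t labels the grid points in
#' the half-open span from the previous event (exclusive) up to and
#' including t; grid points after the last event are \code{NA}.
#'
#' @param rts Data frame with \code{time_s} (stimulus onset) and
#'   \code{rt_ms}.
#' @param grid_times Numeric vector of detection grid times (seconds).
#' @return List with \code{labels} (logical along \code{grid_times}),
#'   \code{threshold} (ms) and \code{event_labels} (per-event logical),
#'   recorded for audit.
#' @export
label_inattention <- function(rts, grid_times) {
  stopifnot(is.data.frame(rts), all(c("time_s", "rt_ms") %in% names(rts)))
  if (nrow(rts) < 2) stop("need at least 2 reaction-time events")
  o <- order(rts$time_s)
  tm <- rts$time_s[o]; rt <- rts$rt_ms[o]
  thr <- mean(rt) + sd(rt)
  ev <- rt >= thr
  ## grid point g belongs to the first event at time >= g
  idx <- length(tm) + 1 - findInterval(-grid_times, rev(-tm))
  lab <- rep(NA, length(grid_times))
  ok <- idx <= length(tm)
  lab[ok] <- ev[idx[ok]]
  list(labels = lab, threshold = thr, event_labels = ev)
}

## ---- Evaluation ----------------------------------------------------------

#' Sensitivity/specificity of a state timeline against ground truth
#'
#' Per-grid-point confusion of a predicted timeline against a boolean truth
#' series for one target state. MISSING predictions and \code{NA} truth are
#' excluded from the counts. Optionally a guard band around truth
#' transitions is excluded as well: a causal window that straddles an
#' episode edge mixes both regimes and has no unambiguous label.
#'
#' @param pred Factor of predicted states along the grid (see
#'   \code{\link{fuse_states}}), or a logical vector of per-stage anomaly
#'   votes.
#' @param truth Logical vector along the same grid.
#' @param target Target state, \code{"DROWSINESS"} or \code{"INATTENTION"}
#'   (ignored when \code{pred} is logical).
#' @param grid_times Grid times (needed when \code{guard > 0}).
#' @param guard Seconds excluded on both sides of every truth transition
#'   (default 0).
#' @return Object of class \code{eval_result}: list with \code{sensitivity},
#'   \code{specificity}, \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{n_evaluated}. Sensitivity is \code{NA} (flagged) when the truth
#'   contains no positive samples.
#' @export
evaluate_timeline <- function(pred, truth, target = c("DROWSINESS", "INATTENTION"),
                              grid_times = NULL, guard = 0) {
  if (is.factor(pred) || is.character(pred)) {
    target <- match.arg(target)
    p <- as.character(pred) == target
    p[as.character(pred) == "MISSING"] <- NA
  } else p <- as.logical(pred)
  stopifnot(length(p) == length(truth))
  keep <- !is.na(p) & !is.na(truth)
  if (guard > 0) {
    if (is.null(grid_times)) stop("'grid_times' is required when guard > 0")
    tr <- which(diff(as.integer(truth)) != 0)
    for (i in tr) {
      edge <- (grid_times[i] + grid_times[i + 1]) / 2
      keep <- keep & !(grid_times > edge - guard & grid_times < edge + guard)
    }
  }
  p <- p[keep]; tr <- truth[keep]
  tp <- sum(p & tr); fn <- sum(!p & tr)
  tn <- sum(!p & !tr); fp <- sum(p & !tr)
  structure(
    list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         tp = tp, fp = fp, tn = tn, fn = fn, n_evaluated = length(p)),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("sensitivity %.3f  specificity %.3f  (TP %d, FP %d, TN %d, FN %d; n = %d)\n",
              x$sensitivity, x$specificity, x$tp, x$fp, x$tn, x$fn,
              x$n_evaluated))
  invisible(x)
}

## ---- End-to-end monitor --------------------------------------------------

#' Configuration of the driver-state monitor
#'
#' Collects every numeric choice of the pipeline with its standard default:
#' HRV window 120 s, motion window 60 s, body-movement window 2 s, slide
#' 1 s, 60 sub-windows, Yule-Walker AR order 10, LF band 0.04--0.15 Hz, HF
#' band 0.15--0.4 Hz, 1 retained principal component, 90th-percentile
#' control limit, low-pass cut-off 12.5 Hz of order 3.
#'
#' @param hrv_window,motion_window,bodymove_window Window lengths (s).
#' @param slide Slide interval (s).
#' @param nsw Number of motion sub-windows.
#' @param ar_order AR model order.
#' @param lf_band,hf_band HRV frequency bands (Hz).
#' @param ncomp Retained principal components per model.
#' @param percentile Control-limit calibration percentile.
#' @param lowpass_cutoff,lowpass_order Accelerometer low-pass filter.
#' @param max_missing Maximum in-window RRI missing fraction.
#' @param stages Named logical vector enabling the three stages.
#' @return Named list of class \code{monitor_config}.
#' @export
monitor_config <- function(hrv_window = 120, motion_window = 60,
                           bodymove_window = 2, slide = 1, nsw = 60,
                           ar_order = 10, lf_band = c(0.04, 0.15),
                           hf_band = c(0.15, 0.40), ncomp = 1,
                           percentile = 90, lowpass_cutoff = 12.5,
                           lowpass_order = 3, max_missing = 0.3,
                           stages = c(body_movement = TRUE,
                                      drowsiness = TRUE,
                                      inattention = TRUE)) {
  structure(as.list(environment()), class = "monitor_config")
}

monitor_features <- function(config, rri, left, right, filtered = FALSE) {
  if (!filtered) {
    left <- lowpass_accel(left, config$lowpass_cutoff, config$lowpass_order)
    right <- lowpass_accel(right, config$lowpass_cutoff, config$lowpass_order)
  }
  out <- list()
  if (isTRUE(config$stages[["drowsiness"]]))
    out$drowsiness <- extract_hrv_features(
      rri, window = config$hrv_window, slide = config$slide,
      ar_order = config$ar_order, lf_band = config$lf_band,
      hf_band = config$hf_band, max_missing = config$max_missing)
  if (isTRUE(config$stages[["inattention"]]))
    out$inattention <- extract_motion_features(
      left, right, window = config$motion_window, slide = config$slide,
      nsw = config$nsw)
  if (isTRUE(config$stages[["body_movement"]]))
    out$body_movement <- extract_bodymove_features(
      left, right, window = config$bodymove_window, slide = config$slide)
  out
}

#' Fit a per-participant driver-state monitor
#'
#' Fits one MSPC anomaly model per enabled stage on a recording of normal
#' driving from a single participant (the monitor is user-dependent by
#' design): HRV features for drowsiness, sub-window-difference motion
#' features for inattention, HAR mean/variance features for body movement.
#' Accelerometer input is low-pass filtered before feature extraction.
#'
#' @param rri Training \code{\link{rri_series}} (normal driving).
#' @param left,right Training wrist accelerometer \code{uniform_series}.
#' @param config A \code{\link{monitor_config}}.
#' @return Object of class \code{driver_monitor}: list of fitted
#'   \code{\link{mspc}} models plus the configuration.
#' @export
driver_monitor <- function(rri, left, right, config = monitor_config()) {
  stopifnot(inherits(config, "monitor_config"))
  feats <- monitor_features(config, rri, left, right)
  models <- lapply(feats, function(f) {
    f <- f[stats::complete.cases(f), , drop = FALSE]
    mspc(f, ncomp = config$ncomp, percentile = config$percentile)
  })
  structure(list(models = models, config = config), class = "driver_monitor")
}

#' @export
print.driver_monitor <- function(x, ...) {
  cat("driver_monitor with stage model(s):",
      paste(names(x$models), collapse = ", "), "\n")
  for (nm in names(x$models)) {
    cat(sprintf("-- %s: ", nm)); print(x$models[[nm]])
  }
  invisible(x)
}

## Index of the element of `ref` nearest each element of `x`, or NA when the
## nearest is farther than `tol`.
match_nearest <- function(x, ref, tol) {
  if (!length(ref)) return(rep(NA_integer_, length(x)))
  i <- findInterval(x, ref)
  lo <- pmax(i, 1); hi <- pmin(i + 1, length(ref))
  pick <- ifelse(abs(x - ref[lo]) <= abs(x - ref[hi]), lo, hi)
  pick[abs(x - ref[pick]) > tol] <- NA_integer_
  pick
}

#' Apply a driver-state monitor to a recording
#'
#' Runs feature extraction and per-stage anomaly scoring on a new recording
#' and fuses the stage votes into a per-slide-interval state timeline. All
#' stages are aligned on window END time; the timeline starts once the
#' longest enabled window is available and ends at the shortest stream.
#'
#' @param object A fitted \code{\link{driver_monitor}}.
#' @param rri An \code{\link{rri_series}}.
#' @param left,right Wrist accelerometer \code{uniform_series} (raw; the
#'   monitor applies its own low-pass filter).
#' @param ... Unused.
#' @return Data frame of class \code{state_timeline}: \code{time},
#'   \code{state}, and per-stage \code{<stage>_t2} / \code{<stage>_anomaly}
#'   columns.
#' @export
predict.driver_monitor <- function(object, rri, left, right, ...) {
  config <- object$config
  feats <- monitor_features(config, rri, left, right)
  scored <- lapply(names(object$models), function(nm)
    detect(object$models[[nm]], feats[[nm]]))
  names(scored) <- names(object$models)
  t_start <- max(vapply(scored, function(s) min(s$t_end), 0))
  t_stop <- min(vapply(scored, function(s) max(s$t_end), 0))
  grid <- seq(t_start, t_stop, by = config$slide)
  ## streams may start at slightly different absolute times (the RRI stream
  ## begins at the first beat); align stage windows to the timeline grid by
  ## nearest end time within half a slide interval
  stage_idx <- lapply(scored, function(s)
    match_nearest(grid, s$t_end, tol = config$slide / 2))
  vote <- function(nm) {
    if (is.null(scored[[nm]])) return(rep(NA, length(grid)))
    scored[[nm]]$anomaly[stage_idx[[nm]]]
  }
  tl <- data.frame(time = grid,
                   state = fuse_states(vote("body_movement"),
                                       vote("drowsiness"),
                                       vote("inattention"),
                                       stages = config$stages))
  for (nm in names(scored)) {
    tl[[paste0(nm, "_t2")]] <- scored[[nm]]$t2[stage_idx[[nm]]]
    tl[[paste0(nm, "_anomaly")]] <- scored[[nm]]$anomaly[stage_idx[[nm]]]
  }
  class(tl) <- c("state_timeline", "data.frame")
  tl
}

#' @export
plot.state_timeline <- function(x, ...) {
  st <- as.integer(factor(as.character(x$state), levels = rev(DRIVER_STATES)))
  plot(x$time, st, type = "s", yaxt = "n", xlab = "time [s]", ylab = "",
       ylim = c(1, length(DRIVER_STATES)), ...)
  graphics::axis(2, at = seq_along(DRIVER_STATES), labels = rev(DRIVER_STATES),
                 las = 1, cex.axis = 0.7)
  invisible(x)
}
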