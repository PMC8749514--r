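## Seeded synthetic driving-session generator.
##
## Emulates the statistical structure the detectors assume: an RR-interval
## stream whose LF/HF oscillations and mean level shift during drowsy
## episodes, two wrist accelerometer streams whose steering
## micro-corrections thin out during inattentive episodes, large transients
## for body movements, plus referee drowsiness scores and vigilance-task
## reaction times, all with ground-truth episode labels.

#' Synthetic driving scenario specification
#'
#' Describes one simulated driving session: duration, RNG seed, baseline
#' physiological/motion parameters, and a list of state episodes. Episode
#' strengths are in (0, 1] and scale the deviation from baseline; episode
#' edges are tapered with a raised-cosine ramp to avoid discontinuity
#' artefacts in the autoregressive spectra.
#'
#' @param duration Session length in seconds.
#' @param seed Integer RNG seed (NULL = use current RNG state).
#' @param episodes Data frame with columns \code{kind} (one of
#'   \code{"drowsy"}, \code{"inattentive"}, \code{"body_movement"}),
#'   \code{start}, \code{end} (seconds, within the session) and
#'   \code{strength} in (0, 1]. See \code{\link{episode}}.
#' @param mean_rr Baseline mean RR interval (ms).
#' @param lf_amp,hf_amp Amplitudes (ms) of the 0.10 Hz and 0.30 Hz RR
#'   oscillations (LF/HF band centres).
#' @param rri_noise_sd Per-beat RR noise SD (ms).
#' @param rri_missing_rate Probability that a beat goes undetected.
#' @param pulse_rate Baseline steering micro-correction rate (Hz).
#' @param pulse_amp Micro-correction amplitude (g).
#' @param accel_noise_sd Accelerometer sensor noise SD (g).
#' @param rr_drift_amp Amplitude (ms) of the slow baseline wander of the
#'   mean RR interval (period \code{drift_period}).
#' @param intensity_mod Relative amplitude of the slow common-mode
#'   modulation of movement intensity shared by both wrists (0 = none).
#'   Normal driving is not stationary: overall micro-correction intensity
#'   waxes and wanes over minutes, and this shared mode is the dominant
#'   principal component the anomaly monitor retains.
#' @param drift_period Period (s) of both slow modulations.
#' @param taper Episode edge taper length (s).
#' @return Object of class \code{scenario}.
#' @examples
#' sc <- scenario(duration = 600, seed = 1,
#'                episodes = episode("drowsy", 300, 500, strength = 1))
#' @export
scenario <- function(duration = 2400, seed = NULL,
                     episodes = NULL,
                     mean_rr = 800, lf_amp = 25, hf_amp = 15,
                     rri_noise_sd = 10, rri_missing_rate = 0,
                     pulse_rate = 1.5, pulse_amp = 0.05,
                     accel_noise_sd = 0.01, rr_drift_amp = 10,
                     intensity_mod = 0.25, drift_period = 300, taper = 10) {
  if (is.null(episodes))
    episodes <- data.frame(kind = character(0), start = numeric(0),
                           end = numeric(0), strength = numeric(0))
  stopifnot(duration > 0, mean_rr > 0, lf_amp >= 0, hf_amp >= 0,
            rri_noise_sd >= 0, rri_missing_rate >= 0, rri_missing_rate < 1,
            pulse_rate >= 0, pulse_amp >= 0, accel_noise_sd >= 0,
            rr_drift_amp >= 0, intensity_mod >= 0, intensity_mod < 1,
            drift_period > 0)
  stopifnot(all(c("kind", "start", "end", "strength") %in% names(episodes)))
  if (nrow(episodes)) {
    stopifnot(all(episodes$kind %in% c("drowsy", "inattentive", "body_movement")),
              all(episodes$start >= 0), all(episodes$end <= duration),
              all(episodes$start < episodes$end),
              all(episodes$strength > 0), all(episodes$strength <= 1))
  }
  structure(as.list(environment()), class = "scenario")
}

#' @rdname scenario
#' @param kind Episode kind.
#' @param start,end Episode span in seconds.
#' @param strength Episode strength in (0, 1].
#' @export
episode <- function(kind, start, end, strength = 1) {
  data.frame(kind = kind, start = start, end = end, strength = strength)
}

## Tapered episode strength profile of one kind, evaluated at times t.
strength_profile <- function(spec, kind, t) {
  s <- numeric(length(t))
  ep <- spec$episodes[spec$episodes$kind == kind, , drop = FALSE]
  if (!nrow(ep)) return(s)
  tp <- spec$taper
  for (i in seq_len(nrow(ep))) {
    ramp_in <- pmin(pmax((t - ep$start[i]) / tp, 0), 1)
    ramp_out <- pmin(pmax((ep$end[i] - t) / tp, 0), 1)
    w <- pmin(ramp_in, ramp_out)
    w <- (1 - cos(pi * w)) / 2          # raised cosine
    s <- pmax(s, ep$strength[i] * w)
  }
  s
}

#' Generate a synthetic RR-interval stream
#'
#' Beat times are obtained by integrating an instantaneous RR model:
#' baseline mean plus sinusoidal LF (0.10 Hz) and HF (0.30 Hz) components
#' plus white per-beat noise. During drowsy episodes the HF amplitude and
#' mean RR scale up and the LF amplitude scales down in proportion to
#' episode strength (a parasympathetic-dominance signature). Beats are then
#' dropped independently at the missing rate, merging their intervals, as
#' happens when R peaks go undetected.
#'
#' @param spec A \code{\link{scenario}}. Uses the current RNG state; seed
#'   via \code{\link{simulate_driving}} or \code{set.seed}.
#' @return List with \code{rri} (an \code{\link{rri_series}}) and
#'   \code{truth} (data frame \code{time}, \code{drowsy} strength on a 1 s
#'   grid).
#' @export
gen_rri <- function(spec) {
  stopifnot(inherits(spec, "scenario"))
  ph <- runif(3, 0, 2 * pi)
  n_max <- ceiling(spec$duration / (0.3 * spec$mean_rr / 1000)) + 2
  beats <- numeric(n_max)
  t <- 0; k <- 1
  noise <- rnorm(n_max, 0, spec$rri_noise_sd)
  while (t < spec$duration && k < n_max) {
    sdrw <- strength_profile(spec, "drowsy", t)
    ## slow vagal-tone wander: lengthens the mean RR and raises the HF
    ## (respiratory) amplitude together, the normal-state counterpart of
    ## the parasympathetic-dominance signature of a drowsy episode
    tone <- sin(2 * pi * t / spec$drift_period + ph[3])
    rr <- (spec$mean_rr + spec$rr_drift_amp * tone) * (1 + 0.1 * sdrw) +
      spec$lf_amp * (1 - 0.8 * sdrw) * sin(2 * pi * 0.10 * t + ph[1]) +
      spec$hf_amp * (1 + 0.3 * tone) * (1 + 2.0 * sdrw) *
        sin(2 * pi * 0.30 * t + ph[2]) +
      noise[k]
    rr <- max(rr, 300)
    t <- t + rr / 1000
    k <- k + 1
    beats[k] <- t
  }
  beats <- beats[seq_len(k)]
  keep <- c(TRUE, runif(length(beats) - 1) >= spec$rri_missing_rate)
  beats <- beats[keep]
  rri <- rri_series(beat_times = beats[-1], intervals = diff(beats) * 1000)
  grid <- seq(0, spec$duration, by = 1)
  list(rri = rri,
       truth = data.frame(time = grid,
                          drowsy = strength_profile(spec, "drowsy", grid)))
}

## One wrist: gravity + Poisson-timed smooth micro-correction pulses +
## optional body-movement transients + sensor noise.
gen_wrist <- function(spec, tgrid, gravity, bm_ep, mod_phase = 0) {
  n <- length(tgrid)
  rate <- spec$pulse_rate
  sig <- matrix(rnorm(3 * n, 0, spec$accel_noise_sd), n, 3)
  sig <- sweep(sig, 2, gravity, "+")
  if (rate > 0 && spec$pulse_amp > 0) {
    ## inhomogeneous Poisson pulses by thinning: the common-mode intensity
    ## modulation (shared by both wrists) scales the rate, and inattentive
    ## episodes thin it further
    rate_mod <- spec$intensity_mod
    amp_mod <- spec$intensity_mod / 2
    rate_max <- rate * (1 + rate_mod)
    n_ev <- stats::rpois(1, rate_max * spec$duration)
    ev_t <- sort(runif(n_ev, 0, spec$duration))
    s_atv <- strength_profile(spec, "inattentive", ev_t)
    carrier <- sin(2 * pi * ev_t / spec$drift_period + mod_phase)
    keep <- runif(n_ev) <
      ((1 + rate_mod * carrier) / (1 + rate_mod)) * (1 - 0.9 * s_atv)
    ev_t <- ev_t[keep]; s_atv <- s_atv[keep]; carrier <- carrier[keep]
    fs <- 1 / (tgrid[2] - tgrid[1])
    for (j in seq_along(ev_t)) {
      width <- runif(1, 0.2, 0.5)
      amp <- spec$pulse_amp * (1 + amp_mod * carrier[j]) *
        (1 - 0.9 * s_atv[j])
      i0 <- floor((ev_t[j] - tgrid[1]) * fs) + 1
      m <- max(3, round(width * fs))
      idx <- i0:min(i0 + m - 1, n)
      pulse <- amp * (1 - cos(2 * pi * seq_along(idx) / m)) / 2
      gains <- runif(3, 0.3, 1) * sample(c(-1, 1), 3, replace = TRUE)
      sig[idx, ] <- sig[idx, ] + outer(pulse, gains)
    }
  }
  if (nrow(bm_ep)) {
    fs <- 1 / (tgrid[2] - tgrid[1])
    for (i in seq_len(nrow(bm_ep))) {
      idx <- which(tgrid >= bm_ep$start[i] & tgrid < bm_ep$end[i])
      if (!length(idx)) next
      m <- length(idx)
      pulse <- bm_ep$strength[i] * 1.0 * (1 - cos(2 * pi * seq_len(m) / m)) / 2
      gains <- runif(3, 0.5, 1) * sample(c(-1, 1), 3, replace = TRUE)
      sig[idx, ] <- sig[idx, ] + outer(pulse, gains)
    }
  }
  sig
}

#' Generate synthetic two-wrist accelerometer streams
#'
#' 100 Hz tri-axial signals per wrist: a constant gravity/posture offset,
#' Poisson-timed smooth steering micro-correction pulses, sensor noise, and
#' (optionally) large 1--3 s body-movement transients. Inattentive episodes
#' thin the pulse rate and shrink the pulse amplitude in proportion to
#' episode strength, so the sub-window difference distribution concentrates
#' near zero. Body-movement episodes are injected on one wrist (alternating
#' per episode).
#'
#' @inheritParams gen_rri
#' @param rate Sampling rate (Hz), default 100.
#' @return List with \code{left}, \code{right} (3-channel
#'   \code{\link{uniform_series}}) and \code{truth} (data frame with 1 s grid
#'   columns \code{time}, \code{inattentive} strength, \code{body_movement}
#'   flag).
#' @export
gen_accel <- function(spec, rate = 100) {
  stopifnot(inherits(spec, "scenario"))
  tgrid <- seq(0, spec$duration - 1 / rate, by = 1 / rate)
  bm <- spec$episodes[spec$episodes$kind == "body_movement", , drop = FALSE]
  side <- rep_len(c("left", "right"), max(nrow(bm), 1))
  mod_phase <- runif(1, 0, 2 * pi)
  lw <- gen_wrist(spec, tgrid, c(0.10, -0.20, 0.97),
                  bm[side[seq_len(nrow(bm))] == "left", , drop = FALSE],
                  mod_phase)
  rw <- gen_wrist(spec, tgrid, c(-0.10, 0.20, 0.97),
                  bm[side[seq_len(nrow(bm))] == "right", , drop = FALSE],
                  mod_phase)
  grid <- seq(0, spec$duration, by = 1)
  bm_truth <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(bm)))
    bm_truth <- bm_truth | (grid >= bm$start[i] & grid < bm$end[i])
  list(left = uniform_series(lw, rate, 0, c("L_x", "L_y", "L_z")),
       right = uniform_series(rw, rate, 0, c("R_x", "R_y", "R_z")),
       truth = data.frame(time = grid,
                          inattentive = strength_profile(spec, "inattentive", grid),
                          body_movement = bm_truth))
}

#' Generate synthetic annotation streams
#'
#' Referee drowsiness scores: three simulated referees each rate
#' \code{1 + 3 * drowsy_strength + noise} on a 6-point scale every 5 s; the
#' average of the three is reported. Vigilance-task reaction times: LED
#' onsets at random 2--10 s intervals, with
#' \code{RT = 352.5 + 176 * inattentive_strength + noise} ms, so a
#' strength-1 episode slows responses from the alert anchor (about 352.5 ms)
#' to the inattentive anchor (about 528.5 ms).
#'
#' @inheritParams gen_rri
#' @return List with \code{scores} (data frame \code{time_s}, \code{score},
#'   plus the per-referee columns) and \code{rt} (data frame \code{time_s},
#'   \code{rt_ms}).
#' @export
gen_annotations <- function(spec) {
  stopifnot(inherits(spec, "scenario"))
  st <- seq(0, spec$duration - 5, by = 5)
  sd_mid <- strength_profile(spec, "drowsy", st + 2.5)
  ref <- sapply(1:3, function(i)
    pmin(pmax(1 + 3 * sd_mid + rnorm(length(st), 0, 0.3), 1), 6))
  scores <- data.frame(time_s = st, score = rowMeans(ref),
                       score_1 = ref[, 1], score_2 = ref[, 2],
                       score_3 = ref[, 3])
  ev <- c(); t <- runif(1, 2, 10)
  while (t < spec$duration) { ev <- c(ev, t); t <- t + runif(1, 2, 10) }
  s_atv <- strength_profile(spec, "inattentive", ev)
  rt <- 352.5 + (528.5 - 352.5) * s_atv + rnorm(length(ev), 0, 25)
  list(scores = scores, rt = data.frame(time_s = ev, rt_ms = pmax(rt, 120)))
}

#' Simulate a full driving session
#'
#' Runs all three generators under the scenario's seed (restoring the
#' caller's RNG state afterwards) and bundles their outputs with the
#' ground-truth episode labels. Identical scenarios produce identical
#' sessions.
#'
#' @param spec A \code{\link{scenario}}.
#' @return Object of class \code{driving_session}: list with \code{rri},
#'   \code{left}, \code{right}, \code{scores}, \code{rt}, \code{truth}
#'   (1 s-grid data frame with columns \code{time}, \code{drowsy},
#'   \code{inattentive}, \code{body_movement}) and \code{scenario}.
#' @examples
#' sess <- simulate_driving(scenario(duration = 300, seed = 7))
#' sess$rri
#' @export
simulate_driving <- function(spec) {
  stopifnot(inherits(spec, "scenario"))
  with_seed(spec$seed, {
    hr <- gen_rri(spec)
    ac <- gen_accel(spec)
    an <- gen_annotations(spec)
    truth <- data.frame(time = hr$truth$time,
                        drowsy = hr$truth$drowsy,
                        inattentive = ac$truth$inattentive,
                        body_movement = ac$truth$body_movement)
    structure(list(rri = hr$rri, left = ac$left, right = ac$right,
                   scores = an$scores, rt = an$rt, truth = truth,
                   scenario = spec),
              class = "driving_session")
  })
}

#' @export
print.driving_session <- function(x, ...) {
  cat(sprintf("driving_session: %.0f s, %d beats, %d accel samples/wrist, %d episodes\n",
              x$scenario$duration, length(x$rri$beat_times),
              nrow(x$left$values), nrow(x$scenario$episodes)))
  invisible(x)
}

#' Write a simulated session to CSV files
#'
#' Writes \code{rri.csv}, \code{left.csv}, \code{right.csv},
#' \code{scores.csv}, \code{rt.csv} and \code{truth.csv} into a directory,
#' in the package's standard CSV dialects.
#'
#' @param session A \code{\link{simulate_driving}} result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_session_csv <- function(session, dir) {
  stopifnot(inherits(session, "driving_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_rri_csv(session$rri, file.path(dir, "rri.csv"))
  write_accel_csv(session$left, file.path(dir, "left.csv"))
  write_accel_csv(session$right, file.path(dir, "right.csv"))
  write.csv(session$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  write.csv(session$rt, file.path(dir, "rt.csv"), row.names = FALSE)
  write.csv(session$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
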