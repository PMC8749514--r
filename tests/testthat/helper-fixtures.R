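# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Deterministic RRI series with LF/HF sinusoidal structure, built by the
# same beat-integration scheme as the generator but with fixed phases and
# optional noise, independent of the package's generator code.
make_rri <- function(duration = 400, mean_rr = 800, lf = 25, hf = 15,
                     noise_sd = 0, seed = 42) {
  set.seed(seed)
  t <- 0; beats <- numeric(0)
  while (t < duration) {
    rr <- mean_rr + lf * sin(2 * pi * 0.10 * t) + hf * sin(2 * pi * 0.30 * t) +
      if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
    t <- t + rr / 1000
    beats <- c(beats, t)
  }
  rri_series(beat_times = beats[-1], intervals = diff(beats) * 1000)
}

# Scalar reference implementation of the decision flow, kept deliberately
# naive and sequential.
fuse_oracle <- function(b, d, a, enabled = c(TRUE, TRUE, TRUE)) {
  votes <- list(b, d, a)
  states <- c("BODY_MOVEMENT", "DROWSINESS", "INATTENTION")
  for (k in 1:3) {
    if (!enabled[k]) next
    if (is.na(votes[[k]])) return("MISSING")
    if (votes[[k]]) return(states[k])
  }
  "NORMAL"
}

# Small normal-driving session shared across tests.
small_session <- function() fixture("small_session", function()
  simulate_driving(scenario(duration = 400, seed = 11)))

# Session with one strong episode of each kind.
episode_session <- function() fixture("episode_session", function()
  simulate_driving(scenario(
    duration = 900, seed = 12,
    episodes = rbind(episode("drowsy", 500, 700, 1),
                     episode("inattentive", 720, 880, 1),
                     episode("body_movement", 450, 452, 1)))))
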