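test_that("state fusion is exhaustively correct over all vote combinations", {
  vals <- list(TRUE, FALSE, NA)
  for (b in vals) for (d in vals) for (a in vals) {
    expect_identical(as.character(fuse_states(b, d, a)),
                     fuse_oracle(b, d, a),
                     info = sprintf("votes (%s, %s, %s)", b, d, a))
    # feasibility configuration: body-movement stage disabled
    expect_identical(
      as.character(fuse_states(b, d, a,
                               stages = c(body_movement = FALSE,
                                          drowsiness = TRUE,
                                          inattention = TRUE))),
      fuse_oracle(b, d, a, enabled = c(FALSE, TRUE, TRUE)))
  }
  # spot checks straight from the flow definition
  expect_identical(as.character(fuse_states(TRUE, TRUE, TRUE)), "BODY_MOVEMENT")
  expect_identical(as.character(fuse_states(FALSE, FALSE, FALSE)), "NORMAL")
  expect_identical(as.character(fuse_states(FALSE, TRUE, FALSE)), "DROWSINESS")
})

test_that("fusion is vectorised and a pure function of its inputs", {
  b <- c(TRUE, FALSE, FALSE, NA)
  d <- c(TRUE, TRUE, FALSE, FALSE)
  a <- c(TRUE, FALSE, TRUE, TRUE)
  out <- fuse_states(b, d, a)
  expect_identical(as.character(out),
                   c("BODY_MOVEMENT", "DROWSINESS", "INATTENTION", "MISSING"))
  expect_identical(fuse_states(b, d, a), out)
})

test_that("drowsiness labeling applies the inclusive 2.0 threshold on 5 s bins", {
  sc <- data.frame(time_s = c(0, 5, 10, 15), score = c(1.0, 2.0, 1.9, 3.2))
  grid <- seq(0, 19, by = 1)
  lab <- label_drowsiness(sc, grid)
  expect_identical(lab, rep(c(FALSE, TRUE, FALSE, TRUE), each = 5))

  # per-referee columns are averaged first: (1, 2, 3) -> 2.0 -> drowsy
  sc3 <- data.frame(time_s = 0, score_1 = 1, score_2 = 2, score_3 = 3)
  expect_true(label_drowsiness(sc3, 0))
  expect_error(label_drowsiness(data.frame(time_s = 0, score = 6.5), 0),
               "\\[1, 6\\]")
})

test_that("inattention labeling uses mean + 1 sample SD, inclusive", {
  # degenerate: zero spread, threshold equals every RT, all inclusive-positive
  rts <- data.frame(time_s = c(5, 10, 15), rt_ms = c(300, 300, 300))
  out <- label_inattention(rts, grid_times = 0:15)
  expect_equal(out$threshold, 300)
  expect_true(all(out$event_labels))
  expect_true(all(out$labels[1:15]))

  rts2 <- data.frame(time_s = c(3, 6, 9, 12), rt_ms = c(200, 300, 400, 600))
  out2 <- label_inattention(rts2, grid_times = 0:12)
  expect_equal(out2$threshold, 375 + sd(c(200, 300, 400, 600)))
  expect_identical(out2$event_labels, c(FALSE, FALSE, FALSE, TRUE))
  # the slow event at t = 12 labels grid points after the previous event
  expect_true(all(out2$labels[11:13]))
  expect_false(any(out2$labels[1:10]))
})

test_that("inattention labels are invariant to a common RT shift", {
  set.seed(51)
  rts <- data.frame(time_s = sort(runif(20, 0, 100)),
                    rt_ms = 350 + rexp(20, 1 / 60))
  a <- label_inattention(rts, 0:100)
  rts$rt_ms <- rts$rt_ms + 250
  b <- label_inattention(rts, 0:100)
  expect_identical(a$labels, b$labels)
  expect_equal(b$threshold - a$threshold, 250)
})

test_that("evaluation reproduces confusion-matrix arithmetic", {
  truth <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  pred <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  # TP = 3, FN = 1, FP = 2, TN = 2
  ev <- evaluate_timeline(pred, truth)
  expect_equal(ev$sensitivity, 0.75)
  expect_equal(ev$specificity, 0.5)
  expect_equal(ev$tp + ev$fp + ev$tn + ev$fn, ev$n_evaluated)

  perfect <- evaluate_timeline(truth, truth)
  expect_equal(c(perfect$sensitivity, perfect$specificity), c(1, 1))
  inverted <- evaluate_timeline(!truth, truth)
  expect_equal(c(inverted$sensitivity, inverted$specificity), c(0, 0))
})

test_that("evaluation excludes MISSING, honours guard bands, flags no-positive truth", {
  pred <- factor(c("DROWSINESS", "MISSING", "NORMAL", "DROWSINESS"),
                 levels = c("BODY_MOVEMENT", "DROWSINESS", "INATTENTION",
                            "NORMAL", "MISSING"))
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  ev <- evaluate_timeline(pred, truth, target = "DROWSINESS")
  expect_equal(ev$n_evaluated, 3)
  expect_equal(ev$fp, 1)

  # guard of 2 s removes grid points around the single truth transition
  truth2 <- c(rep(FALSE, 10), rep(TRUE, 10))
  pred2 <- truth2
  ev2 <- evaluate_timeline(pred2, truth2, grid_times = 1:20, guard = 2)
  expect_equal(ev2$n_evaluated, 20 - 4)
  expect_equal(ev2$sensitivity, 1)

  none <- evaluate_timeline(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_true(is.na(none$sensitivity))
  expect_equal(none$specificity, 0.5)
})

test_that("a fitted monitor produces a deterministic, aligned timeline", {
  sess <- episode_session()
  cfg <- monitor_config(stages = c(body_movement = FALSE, drowsiness = TRUE,
                                   inattention = TRUE))
  train_end <- 430
  trim <- function(s, tmax) {
    s$values <- s$values[sample_times(s) < tmax, , drop = FALSE]; s
  }
  rri_tr <- with(sess$rri, rri_series(beat_times[beat_times < train_end],
                                      intervals[beat_times < train_end]))
  mon <- driver_monitor(rri_tr, trim(sess$left, train_end),
                        trim(sess$right, train_end), cfg)
  expect_s3_class(mon$models$drowsiness, "mspc")
  expect_length(mon$models$drowsiness$feature_names, 8)
  expect_length(mon$models$inattention$feature_names, 18)

  tl <- predict(mon, sess$rri, sess$left, sess$right)
  tl2 <- predict(mon, sess$rri, sess$left, sess$right)
  expect_identical(tl, tl2)
  expect_s3_class(tl$state, "factor")
  expect_equal(diff(tl$time), rep(cfg$slide, nrow(tl) - 1), tolerance = 1e-9)
  # no body-movement stage: that state never appears
  expect_false("BODY_MOVEMENT" %in% tl$state)
  # the strong drowsy episode is flagged as DROWSINESS on the timeline
  mid <- tl$time > 640 & tl$time < 700
  expect_gt(mean(tl$state[mid] == "DROWSINESS"), 0.8)
})

test_that("the full three-stage flow gives body movement priority", {
  sess <- episode_session()
  cfg <- monitor_config()
  train_end <- 430
  trim <- function(s, tmax) {
    s$values <- s$values[sample_times(s) < tmax, , drop = FALSE]; s
  }
  rri_tr <- with(sess$rri, rri_series(beat_times[beat_times < train_end],
                                      intervals[beat_times < train_end]))
  mon <- driver_monitor(rri_tr, trim(sess$left, train_end),
                        trim(sess$right, train_end), cfg)
  tl <- predict(mon, sess$rri, sess$left, sess$right)
  # during the injected transient (450-452 s) body movement wins the flow
  bm_win <- tl$time >= 451 & tl$time <= 453
  expect_true(any(tl$state[bm_win] == "BODY_MOVEMENT"))
})
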