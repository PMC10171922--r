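test_that("total velocity matches analytic speeds on constructed motions", {
  t <- seq(0, 5, by = 0.1)
  expect_true(all(total_velocity(make_stream(t = t, x = 1, y = 2))$speed == 0))

  lin <- total_velocity(make_stream(t = t, x = t))
  expect_equal(lin$speed, rep(1, length(t)), tolerance = 1e-12)

  # circular motion: speed -> r*omega; within 1% at 60 Hz for omega = 2*pi
  r <- 0.2; om <- 2 * pi
  t60 <- seq(0, 3, by = 1 / 60)
  circ <- total_velocity(make_stream(t = t60, x = r * cos(om * t60),
                                     y = r * sin(om * t60)))
  mid <- circ$speed[5:(length(t60) - 5)]
  expect_true(all(abs(mid - r * om) / (r * om) < 0.01))

  expect_error(total_velocity(make_stream(t = c(0, 1, 3), x = 1:3)),
               "uniform")
})

test_that("angular speed is computed on the circle", {
  # steady 100 deg/s rotation crossing the seam
  t <- seq(0, 4, by = 0.1)
  a <- wrap_head_angles(data.frame(t = t, rx = (100 * t) %% 360,
                                   ry = 0 * t, rz = 0 * t))
  v <- total_velocity(a, angular = TRUE)
  expect_equal(max(abs(v$speed - 100)), 0, tolerance = 1e-9)
})

test_that("invalidity propagates to adjacent speed samples", {
  t <- seq(0, 1, by = 0.1)
  s <- make_stream(t = t, x = t)
  s$valid <- rep(TRUE, 11); s$valid[5] <- FALSE
  v <- total_velocity(s)
  expect_equal(which(!v$valid), 4:6)
})

test_that("Freedman-Diaconis edges follow the midpoint-quartile rule", {
  e <- fd_bin_edges(1:8)
  expect_equal(attr(e, "h"), 2 * 4 * 8^(-1 / 3))  # IQR = 4, h = 4
  expect_equal(as.numeric(e), c(0, 4, 8))
  # independent check of the quartile convention
  expect_equal(diff(unname(quantile(1:8, c(.25, .75), type = 5))), 4.5 - 0.5)

  # scale equivariance of the width
  e2 <- fd_bin_edges(3 * (1:8))
  expect_equal(attr(e2, "h"), 3 * attr(e, "h"))

  # tied data falls back to an SD-based width
  ef <- fd_bin_edges(c(rep(2, 96), 1, 9, 2, 2))
  expect_equal(attr(ef, "rule"), "scott-fallback")
  expect_error(fd_bin_edges(c(1, 2, 3)), "at least 4")
})

test_that("velocity histograms are normalized distributions with valid CDFs", {
  edges <- c(0, 1, 2, 3)
  vd <- velocity_histogram(c(1.2, 1.5, 1.9), edges, "hand")
  expect_equal(vd$pdf, c(0, 1, 0))
  expect_equal(vd$cdf, c(0, 0, 1, 1))

  set.seed(42)
  x <- rexp(1e5, rate = 2)
  e <- fd_bin_edges(x)
  vd2 <- velocity_histogram(x, e, "gaze")
  expect_equal(sum(vd2$pdf), 1, tolerance = 1e-12)
  expect_true(all(diff(vd2$cdf) >= 0))
  expect_equal(vd2$cdf[length(vd2$cdf)], 1)
  mids <- (e[-1] + e[-length(e)]) / 2
  expect_lt(abs(sum(mids * vd2$pdf) - 0.5) / 0.5, 0.02)
  expect_error(velocity_histogram(numeric(0), edges), "valid")
})

test_that("saccade detection applies velocity, acceleration and distance rules", {
  t <- seq(0, 5, by = 1 / 60)
  still <- make_gaze(t, x = rep(0.4, length(t)), y = rep(0.4, length(t)))
  expect_equal(nrow(detect_saccades(still)), 0)

  # one instantaneous 0.2 a.u. jump -> exactly one event
  x <- rep(0.3, length(t)); x[t > 2.5] <- 0.5
  ev <- detect_saccades(make_gaze(t, x, y = rep(0.5, length(t))))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$distance, 0.2, tolerance = 1e-9)
  expect_gt(ev$peak_acceleration, 90)

  # same event shifted by a constant offset: identical detection
  ev2 <- detect_saccades(make_gaze(t, x + 0.17, y = rep(0.2, length(t))))
  expect_equal(ev2$onset, ev$onset)
  expect_equal(ev2$distance, ev$distance, tolerance = 1e-12)

  # tiny 0.004 a.u. movement: below the velocity gate at default config
  x3 <- rep(0.3, length(t)); x3[t > 2.5] <- 0.304
  g3 <- make_gaze(t, x3, y = rep(0.5, length(t)))
  expect_equal(nrow(detect_saccades(g3)), 0)
  # with velocity/acceleration gates opened, the path-distance rule alone
  # still rejects it (0.004 < 0.005 a.u.) ...
  expect_equal(nrow(detect_saccades(g3, velocity_threshold = 0.1,
                                    accel_threshold = 1)), 0)
  # ... and passes a 0.2 a.u. event under the same relaxed gates
  expect_equal(nrow(detect_saccades(make_gaze(t, x, rep(0.5, length(t))),
                                    velocity_threshold = 0.1,
                                    accel_threshold = 1)), 1)

  # sub-threshold slow drift -> no events
  drift <- make_gaze(t, x = 0.3 + 0.02 * t, y = rep(0.5, length(t)))
  expect_equal(nrow(detect_saccades(drift)), 0)
  expect_error(detect_saccades(make_gaze(t[1:2], c(0, 0), c(0, 0))),
               "3 samples")
})

test_that("saccade rate and mean speed are simple valid-time ratios", {
  ev <- data.frame(onset = 1:12, offset = 1:12 + 0.02)
  expect_equal(saccade_rate(ev, 60), 0.2)
  expect_equal(saccade_rate(ev[0, ], 60), 0)
  expect_error(saccade_rate(ev, 0), "positive")
  expect_equal(mean_speed(c(1, 2, 3)), 2)
})

test_that("task measures summarise each round of the trial log", {
  log <- data.frame(
    round = rep(1:2, c(4, 3)),
    trial_index = c(1:4, 1:3),
    time_first_decision = c(5, 7, 9, 3, 2, 4, 6),
    opportunity_offered = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    changed = c(TRUE, FALSE, NA, TRUE, NA, NA, NA),
    time_second_decision = c(2, 3, NA, 4, NA, NA, NA))
  tm <- task_measures(log)
  expect_equal(tm$ratio_changed[1], 2 / 3)
  expect_equal(tm$mean_time_first[1], 6)
  expect_equal(tm$mean_time_second[1], 3)
  expect_equal(tm$total_time[1], 24 + 9)
  expect_gte(tm$total_time[1], max(log$time_first_decision[log$round == 1]))
  # round 2 offered no opportunities: ratio undefined
  expect_true(is.na(tm$ratio_changed[2]))
  expect_equal(tm$mean_time_first[2], 4)
  expect_error(task_measures(data.frame(round = 1)), "malformed")
})
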