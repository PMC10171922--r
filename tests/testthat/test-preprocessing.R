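test_that("gaze filter keeps confidence >= 0.6 and in-frame coordinates", {
  g <- make_gaze(t = 1:5 / 10, x = rep(0.5, 5), y = rep(0.5, 5),
                 confidence = c(0.9, 0.5, 0.61, 0.6, 0.59))
  kept <- filter_gaze(g)
  expect_equal(kept$confidence, c(0.9, 0.61, 0.6))

  g2 <- make_gaze(t = c(0.1, 0.2), x = c(1.01, 0.5), y = c(0.5, -0.001))
  expect_equal(nrow(filter_gaze(g2)), 0)

  empty <- make_gaze(numeric(0), numeric(0), numeric(0), numeric(0))
  expect_equal(nrow(filter_gaze(empty)), 0)
  expect_error(filter_gaze(data.frame(t = 1, x = 0.5, y = 0.5)),
               "confidence")
  # idempotence
  expect_identical(filter_gaze(kept), kept)
})

test_that("head angles wrap from [0, 360) to [-180, 180)", {
  h <- data.frame(t = 1:4 / 10, rx = c(359, 180, 0, 179.5),
                  ry = c(360.5, 725, 0, 90), rz = rep(10, 4))
  w <- wrap_head_angles(h)
  expect_equal(w$rx, c(-1, -180, 0, 179.5))
  expect_equal(w$ry, c(0.5, 5, 0, 90))
  expect_true(all(w$rx >= -180 & w$rx < 180))
  # idempotence on already-wrapped data
  expect_equal(wrap_head_angles(w), w)
})

test_that("resampling interpolates linearly and flags long gaps invalid", {
  s <- make_stream(t = c(0, 1), v = c(0, 10))
  r <- resample_stream(s, rate = 10, max_gap = 2)
  expect_equal(nrow(r), 11)
  expect_equal(r$v, seq(0, 10, by = 1))

  const <- make_stream(t = seq(0, 5, by = 0.21), v = 3)
  rc <- resample_stream(const, rate = 10)
  expect_true(all(rc$v == 3))
  expect_true(all(rc$valid))

  # a 2 s hole with max_gap 0.5 s: grid samples inside are invalid
  tt <- c(seq(0, 2, by = 0.1), seq(4, 6, by = 0.1))
  rg <- resample_stream(make_stream(t = tt, v = sin(tt)), rate = 10,
                        max_gap = 0.5)
  inside <- rg$t > 2.05 & rg$t < 3.95
  expect_true(all(!rg$valid[inside]))
  expect_true(all(rg$valid[rg$t < 1.95]))
  expect_error(resample_stream(make_stream(t = 1, v = 1), 10), "2 samples")
})

test_that("angular resampling crosses the +/-180 seam without sweeps", {
  # head turning through 0 deg: wrapped values jump 179 -> -179
  s <- data.frame(t = c(0, 0.1, 0.2, 0.3), a = c(178, 179, -179, -178))
  r <- resample_stream(s, rate = 40, angular = TRUE)
  # interpolated path stays near the seam, never near 0
  expect_true(all(abs(r$a) > 170))
})

test_that("hand trimming removes exactly 2 s from each end", {
  h <- make_stream(t = seq(0, 10, by = 0.1), x = 0)
  tr <- trim_hand(h)
  expect_equal(nrow(tr), 61)
  expect_equal(range(tr$t), c(2, 8))
  short <- make_stream(t = seq(0, 4.1, by = 0.1), x = 0)
  expect_equal(diff(range(trim_hand(short)$t)), 0.1, tolerance = 1e-9)
  expect_error(trim_hand(make_stream(t = seq(0, 3, by = 0.1), x = 0)),
               "shorter")
  expect_identical(trim_hand(tr, trim = 0), tr)
})

test_that("alignment intersects supports and ANDs validity masks", {
  t <- seq(0, 100, by = 0.05)
  hand <- make_stream(t = t, x = sin(t), y = cos(t), z = t / 100)
  gaze <- make_gaze(t = t, x = 0.5 + 0.3 * sin(t), y = 0.5 + 0.3 * cos(t))
  head <- make_stream(t = t, rx = 10 * sin(t), ry = 5 * cos(t), rz = 0 * t + 1)
  al <- align_streams(hand, gaze, head)
  expect_s3_class(al, "aligned_recording")
  expect_true(all(al$valid))
  expect_equal(ncol(al), 10)  # t + 8 channels + valid

  # gaze missing on [10, 20]: joint mask false there
  gz <- gaze[gaze$t < 10 | gaze$t > 20, ]
  al2 <- align_streams(hand, gz, head)
  expect_true(all(!al2$valid[al2$t > 10.2 & al2$t < 19.8]))
  expect_true(all(al2$valid[al2$t < 9.8]))

  g_late <- gaze; g_late$t <- g_late$t + 200
  expect_error(align_streams(hand, g_late, head), "overlap")
})

test_that("exclusion bookkeeping follows the 60 s and questionnaire rules", {
  v <- data.frame(id = c("a", "b", "c", "d"),
                  gaze = c(59, 80, 100, 70), hand = c(70, 70, 61, 80),
                  head = c(65, 100, 100, 90), joint = c(55, 70, 60, 65),
                  questionnaire_minutes = c(80, 61, 90, 62))
  res <- apply_exclusions(v)
  # a: 59 s gaze -> excluded from gaze (and joint at 55 s), kept for head
  expect_false(res$retained$gaze[1])
  expect_false(res$retained$joint[1])
  expect_true(res$retained$head[1])
  expect_true(res$retained$hand[1])
  # b: questionnaire under 62 minutes -> excluded everywhere
  expect_false(any(unlist(res$retained[2, -1])))
  # d: boundary questionnaire time kept
  expect_true(res$retained$gaze[4])
  # counts: retained + excluded = input per modality
  for (m in c("gaze", "hand", "head", "joint")) {
    pm <- res$report$per_modality[[m]]
    expect_equal(pm$retained + pm$excluded, res$report$n_input)
  }
  all_ok <- data.frame(id = "x", gaze = 61, hand = 61, head = 61, joint = 61,
                       questionnaire_minutes = 100)
  expect_true(all(unlist(apply_exclusions(all_ok)$retained[, -1])))
})

test_that("resampling a band-limited signal preserves mean speed within 5%", {
  # 0.5 Hz sinusoid sampled at 37 Hz, resampled to 10 Hz; analytic mean
  # speed of A*sin(2*pi*f*t) is 4*A*f
  t <- seq(0, 60, by = 1 / 37)
  A <- 0.3; f <- 0.5
  s <- make_stream(t = t, x = A * sin(2 * pi * f * t))
  r <- resample_stream(s, rate = 10)
  v <- total_velocity(r)
  expect_lt(abs(mean_speed(v) - 4 * A * f) / (4 * A * f), 0.05)
})
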