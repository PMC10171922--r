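test_that("cohort generation is deterministic and validates its spec", {
  spec <- cohort_spec(n_participants = 6, seed = 11)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  rec1 <- generate_recording(generate_cohort(spec)[[2]]$params, 120, seed = 3)
  rec2 <- generate_recording(generate_cohort(spec)[[2]]$params, 120, seed = 3)
  expect_identical(rec1, rec2)
  log1 <- generate_task_log(generate_cohort(spec)[[1]]$params, seed = 5)
  expect_identical(log1, generate_task_log(generate_cohort(spec)[[1]]$params,
                                           seed = 5))
  expect_error(cohort_spec(n_participants = 1), "n_participants")
  expect_error(cohort_spec(effect_hand_velocity = Inf), "finite")
  expect_error(generate_recording(generate_cohort(spec)[[1]]$params,
                                  duration = 60), "duration")
})

test_that("trait scores stay on the 0-100 scale and drive parameters with the planted sign", {
  spec <- cohort_spec(n_participants = 200, trait_mean = 50, trait_sd = 40,
                      seed = 2)
  traits <- vapply(generate_cohort(spec), `[[`, 0, "trait")
  expect_true(all(traits >= 0 & traits <= 100))

  # planted negative hand-velocity slope: negative sample correlation in
  # nearly all seeds
  neg <- vapply(1:100, function(s) {
    co <- generate_cohort(cohort_spec(n_participants = 32,
                                      effect_hand_velocity = -0.5, seed = s))
    tr <- vapply(co, `[[`, 0, "trait")
    hs <- vapply(co, function(p) p$params$hand_speed_factor, 0)
    cor(tr, hs) < 0
  }, TRUE)
  expect_gte(mean(neg), 0.95)
})

test_that("null-effect specs produce null trait-parameter associations", {
  ps <- vapply(1:100, function(s) {
    co <- generate_cohort(cohort_spec(
      n_participants = 50, effect_hand_velocity = 0, effect_head_velocity = 0,
      effect_gaze_velocity = 0, effect_saccade_rate = 0,
      effect_change_ratio = 0, effect_coordination_stability = 0, seed = s))
    tr <- vapply(co, `[[`, 0, "trait")
    hs <- vapply(co, function(p) p$params$hand_speed_factor, 0)
    cor.test(tr, hs)$p.value
  }, 0)
  expect_gte(mean(ps > 0.05), 0.90)
})

test_that("raw recordings have the promised stream structure", {
  params <- generate_cohort(cohort_spec(n_participants = 2, seed = 4))[[1]]$params
  rec <- generate_recording(params, duration = 120, seed = 9)
  for (mod in c("hand", "gaze", "head")) {
    expect_true(all(diff(rec[[mod]]$t) > 0))
  }
  expect_true(all(rec$gaze$confidence >= 0 & rec$gaze$confidence <= 1))
  # a configurable fraction of gaze samples is unusable
  bad <- rec$gaze$confidence < 0.6 | rec$gaze$x < 0 | rec$gaze$x > 1 |
    rec$gaze$y < 0 | rec$gaze$y > 1
  expect_gt(mean(bad), 0)
  expect_true(all(rec$head$rx >= 0 & rec$head$rx < 360))
})

test_that("zero missingness yields an all-valid preprocessed record", {
  params <- generate_cohort(cohort_spec(n_participants = 2, seed = 4))[[1]]$params
  rec <- generate_recording(params, duration = 120, seed = 10,
                            gaze_gap_rate = 0, low_conf_frac = 0,
                            hand_gap_rate = 0)
  prep <- preprocess_recording(rec)
  expect_true(all(prep$gaze60$valid))
  expect_true(all(prep$hand10$valid))
  expect_true(all(prep$head10$valid))
  expect_true(all(prep$aligned$valid))
})

test_that("uncoupled modalities produce near-diagonal coordination matrices", {
  offd <- vapply(1:20, function(s) {
    params <- generate_cohort(cohort_spec(n_participants = 2,
                                          seed = s))[[1]]$params
    params$coupling <- c(0, 0)
    rec <- generate_recording(params, duration = 120, seed = 100 + s,
                              gaze_gap_rate = 0, low_conf_frac = 0,
                              hand_gap_rate = 0)
    prep <- preprocess_recording(rec)
    C <- coordination_matrix(prep$aligned)
    mean(abs(C[upper.tri(C)]))
  }, 0)
  expect_lt(mean(offd), 0.15)
})

test_that("task logs respect trial counts, opportunity flags and change probabilities", {
  params <- generate_cohort(cohort_spec(n_participants = 2, seed = 1))[[1]]$params
  log <- generate_task_log(params, seed = 1)
  expect_equal(sum(log$round == 1), 12)
  expect_equal(sum(log$round == 2), 13)
  expect_true(all(is.na(log$changed[!log$opportunity_offered])))
  expect_true(all(!is.na(log$changed[log$opportunity_offered])))

  p0 <- params; p0$change_prob <- c(0, 0)
  tm0 <- task_measures(generate_task_log(p0, seed = 2))
  expect_true(all(tm0$ratio_changed[tm0$n_opportunities > 0] == 0))
  p1 <- params; p1$change_prob <- c(1, 1)
  tm1 <- task_measures(generate_task_log(p1, seed = 2))
  expect_true(all(tm1$ratio_changed[tm1$n_opportunities > 0] == 1))

  # law of large numbers at p = 1/2 over ~10,000 trials
  ph <- params; ph$change_prob <- c(0.5, 0.5)
  changed <- unlist(lapply(1:400, function(s) {
    l <- generate_task_log(ph, seed = s)
    l$changed[l$opportunity_offered]
  }))
  expect_gt(length(changed), 4000)
  expect_lt(abs(mean(changed) - 0.5), 0.02)
})
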