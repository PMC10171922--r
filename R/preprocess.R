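#' Filter gaze samples by confidence and world-frame range
#'
#' Removes gaze samples whose position-estimation confidence is below 0.6 or
#' whose coordinates fall outside the normalized world frame \[0, 1\]
#' (either indicates the tracker lost the eye or gaze left the display).
#' Removed samples become gaps; nothing is interpolated here.
#'
#' @param gaze data frame with columns `t`, `x`, `y`, `confidence`.
#' @param min_confidence retention threshold; samples with confidence
#'   strictly below it are dropped (boundary samples are kept).
#' @return the retained rows, same columns.
#' @export
filter_gaze <- function(gaze, min_confidence = 0.6) {
  stop_if(is.null(gaze$confidence), "gaze stream has no confidence channel")
  if (nrow(gaze) == 0) return(gaze)
  keep <- gaze$confidence >= min_confidence &
    gaze$x >= 0 & gaze$x <= 1 & gaze$y >= 0 & gaze$y <= 1
  gaze[keep, , drop = FALSE]
}

#' Re-range head angles from \[0, 360) to \[-180, 180)
#'
#' Angles at or above 180 map down by 360, so 359 becomes -1 and 180 becomes
#' -180 (half-open convention). Values outside \[0, 360) are first reduced
#' modulo 360.
#'
#' @param head data frame with columns `t`, `rx`, `ry`, `rz` (degrees).
#' @return same frame with wrapped angles.
#' @export
wrap_head_angles <- function(head) {
  for (ch in c("rx", "ry", "rz")) {
    a <- head[[ch]] %% 360
    head[[ch]] <- ifelse(a >= 180, a - 360, a)
  }
  head
}

# wrap any angle vector to [-180, 180)
wrap180 <- function(a) ((a + 180) %% 360) - 180

#' Resample a sample stream onto a uniform grid
#'
#' Linear interpolation onto a grid at `rate` Hz spanning the stream's time
#' support. Grid points falling inside a raw inter-sample gap longer than
#' `max_gap` seconds are interpolated anyway but flagged invalid in the
#' returned `valid` column, so downstream stages can ignore them. Angle
#' channels (`angular = TRUE`) are unwrapped onto the real line, interpolated
#' there, and re-wrapped to \[-180, 180), avoiding spurious sweeps across the
#' +/-180 seam.
#'
#' @param stream data frame with column `t` plus value channels.
#' @param rate target rate, Hz.
#' @param max_gap longest raw gap (s) across which interpolation is trusted.
#' @param angular logical: treat all value channels as degrees on the circle.
#' @return data frame `t`, channels, `valid`.
#' @export
resample_stream <- function(stream, rate, max_gap = 0.5, angular = FALSE) {
  stop_if(nrow(stream) < 2, "need at least 2 samples to resample")
  grid <- seq(stream$t[1], stream$t[nrow(stream)], by = 1 / rate)
  interp_onto(stream, grid, max_gap = max_gap, angular = angular)
}

# Linear interpolation of all value channels onto an explicit grid, with a
# validity flag for grid points inside raw gaps longer than max_gap.
interp_onto <- function(stream, grid, max_gap, angular = FALSE) {
  tr <- stream$t
  chans <- setdiff(names(stream), c("t", "valid"))
  out <- data.frame(t = grid)
  for (ch in chans) {
    v <- stream[[ch]]
    if (angular) {
      steps <- wrap180(diff(v))
      v <- v[1] + c(0, cumsum(steps))
    }
    y <- stats::approx(tr, v, xout = grid, ties = "ordered")$y
    out[[ch]] <- if (angular) wrap180(y) else y
  }
  gap_left <- findInterval(grid, tr)
  gap_left[gap_left < 1] <- 1L
  gap_right <- pmin(gap_left + 1L, length(tr))
  gap_len <- tr[gap_right] - tr[gap_left]
  out$valid <- gap_len <= max_gap | grid %in% tr
  out
}

#' Trim the first and last 2 seconds of a hand stream
#'
#' Leap-style hand tracking is unreliable while hands enter and leave the
#' sensor volume, so the stream's first and last `trim` seconds are dropped.
#'
#' @param hand data frame with column `t`.
#' @param trim seconds removed from each end.
#' @return trimmed data frame.
#' @export
trim_hand <- function(hand, trim = 2) {
  stop_if(nrow(hand) == 0, "empty hand stream")
  dur <- max(hand$t) - min(hand$t)
  stop_if(dur <= 2 * trim, "hand stream shorter than ", 2 * trim, " seconds")
  eps <- 1e-9  # guard against float jitter at the trim boundaries
  hand[hand$t >= min(hand$t) + trim - eps &
         hand$t <= max(hand$t) - trim + eps, , drop = FALSE]
}

#' Align the three modalities onto one shared grid
#'
#' Co-resamples hand (x, y, z), gaze (x, y) and head (rx, ry, rz) onto one
#' uniform grid at `rate` Hz (default 10 Hz, the coarsest analysis rate)
#' restricted to the intersection of the streams' time supports. The joint
#' validity mask is the AND of the per-modality masks.
#'
#' @param hand,gaze,head preprocessed streams (data frames with `t`; gaze
#'   already confidence/range filtered, head already wrapped, hand trimmed).
#'   A `valid` column, if present, is carried through.
#' @param rate shared rate, Hz.
#' @param max_gap passed to [resample_stream()].
#' @return an `aligned_recording`: data frame `t`, `hand_x`, `hand_y`,
#'   `hand_z`, `gaze_x`, `gaze_y`, `head_rx`, `head_ry`, `head_rz`, `valid`.
#' @export
align_streams <- function(hand, gaze, head, rate = 10, max_gap = 0.5) {
  t0 <- max(min(hand$t), min(gaze$t), min(head$t))
  t1 <- min(max(hand$t), max(gaze$t), max(head$t))
  stop_if(t1 - t0 < 1 / rate, "streams do not overlap in time")
  grid <- seq(t0, t1, by = 1 / rate)
  rs_hand <- interp_onto(hand[c("t", "x", "y", "z")], grid, max_gap)
  rs_gaze <- interp_onto(gaze[c("t", "x", "y")], grid, max_gap)
  rs_head <- interp_onto(head[c("t", "rx", "ry", "rz")], grid, max_gap,
                         angular = TRUE)
  out <- data.frame(
    t = grid,
    hand_x = rs_hand$x, hand_y = rs_hand$y, hand_z = rs_hand$z,
    gaze_x = rs_gaze$x, gaze_y = rs_gaze$y,
    head_rx = rs_head$rx, head_ry = rs_head$ry, head_rz = rs_head$rz,
    valid = rs_hand$valid & rs_gaze$valid & rs_head$valid)
  class(out) <- c("aligned_recording", "data.frame")
  attr(out, "rate") <- rate
  out
}

#' Preprocess one raw recording
#'
#' Applies the full per-recording cleaning chain: gaze confidence/range
#' filtering then resampling at 60 Hz; head angle re-ranging then resampling
#' at 10 Hz; hand trimming (2 s each end) then resampling at 10 Hz; and
#' co-resampling of all eight channels at the shared correlation rate.
#'
#' @param rec a `raw_recording` (list with `hand`, `gaze`, `head`).
#' @param gaze_rate,motor_rate,shared_rate analysis rates, Hz.
#' @param max_gap interpolation gap limit, seconds.
#' @return list with `gaze60`, `hand10`, `head10`, `aligned` and per-modality
#'   valid durations (seconds) in `valid_seconds`.
#' @export
preprocess_recording <- function(rec, gaze_rate = 60, motor_rate = 10,
                                 shared_rate = 10, max_gap = 0.5) {
  gz_f <- filter_gaze(rec$gaze)
  stop_if(nrow(gz_f) < 2, "gaze stream empty after filtering")
  gaze60 <- resample_stream(gz_f[c("t", "x", "y")], gaze_rate, max_gap)
  hd_w <- wrap_head_angles(rec$head)
  head10 <- resample_stream(hd_w[c("t", "rx", "ry", "rz")], motor_rate,
                            max_gap, angular = TRUE)
  hn_t <- trim_hand(rec$hand)
  hand10 <- resample_stream(hn_t[c("t", "x", "y", "z")], motor_rate, max_gap)
  aligned <- align_streams(hn_t, gz_f, hd_w, rate = shared_rate,
                           max_gap = max_gap)
  list(gaze60 = gaze60, hand10 = hand10, head10 = head10, aligned = aligned,
       valid_seconds = c(
         gaze = sum(gaze60$valid) / gaze_rate,
         hand = sum(hand10$valid) / motor_rate,
         head = sum(head10$valid) / motor_rate,
         joint = sum(aligned$valid) / shared_rate))
}

#' Apply the study's participant exclusion rules
#'
#' A participant is excluded from a modality's analyses when fewer than
#' `min_valid_seconds` of valid samples survive preprocessing in that
#' modality, and excluded entirely when the questionnaire was completed in
#' under `min_questionnaire_minutes` (insufficiently considered responses).
#' Retention is bookkept separately per modality and jointly, since missing
#' intervals need not align across recordings.
#'
#' @param validity data frame with columns `id`, `gaze`, `hand`, `head`,
#'   `joint` (valid seconds per modality) and `questionnaire_minutes`.
#' @param min_valid_seconds minimum valid recording time, seconds.
#' @param min_questionnaire_minutes minimum questionnaire completion time.
#' @return list: `retained` (logical data frame per modality), `report`
#'   (counts retained/excluded per modality, questionnaire exclusions).
#' @export
apply_exclusions <- function(validity, min_valid_seconds = 60,
                             min_questionnaire_minutes = 62) {
  q_ok <- validity$questionnaire_minutes >= min_questionnaire_minutes
  retained <- data.frame(id = validity$id)
  for (mod in c("gaze", "hand", "head", "joint")) {
    retained[[mod]] <- q_ok & validity[[mod]] >= min_valid_seconds
  }
  n <- nrow(validity)
  report <- list(
    n_input = n,
    questionnaire_excluded = sum(!q_ok),
    per_modality = lapply(stats::setNames(nm = c("gaze", "hand", "head",
                                                 "joint")), function(mod) {
      list(retained = sum(retained[[mod]]),
           excluded = n - sum(retained[[mod]]))
    }))
  list(retained = retained, report = report)
}
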