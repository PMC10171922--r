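#' Specify a synthetic cohort
#'
#' Defines the study conditions for a simulated cohort of trait-scored
#' participants performing the two-round odd-one-out task. Trait scores live
#' on a 0-100 scale (clipped). Effect slopes are standardized: each is the
#' shift, per trait z-score, of the log of the corresponding participant
#' parameter (for `effect_change_ratio`, of the logit of the per-round
#' decision-change probability). Signs of the defaults follow the pattern the
#' analysis is designed to detect: slower hand and head movement, faster gaze
#' with more saccades, fewer decision changes, and more stable between-round
#' coordination at higher trait scores. Magnitudes default to clearly
#' detectable planted effects (trait-parameter correlations near 0.9, which
#' attenuate to roughly 0.6-0.7 after a full recording-level analysis);
#' set all slopes to 0 for null cohorts.
#'
#' @param n_participants number of participants (>= 2).
#' @param trait_mean,trait_sd mean and SD of the trait score before clipping
#'   to \[0, 100\].
#' @param effect_hand_velocity,effect_head_velocity,effect_gaze_velocity
#'   slopes of log mean-speed scale factors per trait z-score.
#' @param effect_saccade_rate slope of the log extra-saccade rate.
#' @param effect_change_ratio slope of the logit decision-change probability.
#' @param effect_coordination_stability slope of the log between-round
#'   coordination-change magnitude (negative = higher trait, more stable).
#' @param param_noise SD of the per-participant lognormal noise on each
#'   generated parameter, on the same log scale as the slopes.
#' @param seed master integer seed; all cohort randomness derives from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 32,
                        trait_mean = 50, trait_sd = 15,
                        effect_hand_velocity = -0.6,
                        effect_head_velocity = -0.6,
                        effect_gaze_velocity = 0.6,
                        effect_saccade_rate = 0.6,
                        effect_change_ratio = -1.0,
                        effect_coordination_stability = -0.6,
                        param_noise = 0.25,
                        seed = 1L) {
  slopes <- c(effect_hand_velocity, effect_head_velocity, effect_gaze_velocity,
              effect_saccade_rate, effect_change_ratio,
              effect_coordination_stability)
  stop_if(!is.numeric(n_participants) || length(n_participants) != 1 ||
            !is.finite(n_participants) || n_participants < 2,
          "n_participants must be a single number >= 2")
  stop_if(any(!is.finite(slopes)), "all effect slopes must be finite")
  stop_if(!is.finite(trait_sd) || trait_sd <= 0, "trait_sd must be > 0")
  structure(list(
    n_participants = as.integer(n_participants),
    trait_mean = trait_mean, trait_sd = trait_sd,
    effect_hand_velocity = effect_hand_velocity,
    effect_head_velocity = effect_head_velocity,
    effect_gaze_velocity = effect_gaze_velocity,
    effect_saccade_rate = effect_saccade_rate,
    effect_change_ratio = effect_change_ratio,
    effect_coordination_stability = effect_coordination_stability,
    param_noise = param_noise,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a cohort of trait-scored participants
#'
#' Draws trait scores and maps them, through the spec's signed effect slopes
#' plus lognormal individual variation, to the participant-level parameters
#' that drive recording and task-log generation: mean-speed scale factors per
#' modality, extra-saccade rate, per-round decision-change probabilities,
#' per-round latent-target coupling strengths, and decision-time medians.
#' Deterministic given the spec's seed; each participant gets an independent
#' substream.
#'
#' @param spec a [cohort_spec()].
#' @return list of participants, each `list(id, trait, params)`.
#' @export
generate_cohort <- function(spec) {
  stop_if(!inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  traits <- with_seed(substream_seed(spec$seed, "traits"), {
    pmin(100, pmax(0, stats::rnorm(spec$n_participants,
                                   spec$trait_mean, spec$trait_sd)))
  })
  lapply(seq_len(spec$n_participants), function(k) {
    z <- (traits[k] - spec$trait_mean) / spec$trait_sd
    with_seed(substream_seed(spec$seed, "params", k), {
      eps <- stats::rnorm(8) * spec$param_noise
      coupling1 <- min(0.9, max(0.25, 0.65 + 0.10 * stats::rnorm(1)))
      # trait-scaled magnitude of the between-round coupling change; the
      # direction points away from the nearer coupling bound so the planted
      # magnitude is not truncated. RD between round matrices grows with it.
      dmag <- 0.22 * exp(spec$effect_coordination_stability * z + eps[6])
      dsign <- sample(c(-1, 1), 1)
      if (coupling1 + dsign * dmag > 0.95 ||
          coupling1 + dsign * dmag < 0.05) dsign <- -dsign
      coupling2 <- min(0.95, max(0.05, coupling1 + dsign * dmag))
      change_logit <- spec$effect_change_ratio * z + 0.5 * stats::rnorm(1)
      params <- list(
        hand_speed_factor = exp(spec$effect_hand_velocity * z + eps[1]),
        head_speed_factor = exp(spec$effect_head_velocity * z + eps[2]),
        gaze_speed_factor = exp(spec$effect_gaze_velocity * z + eps[3]),
        saccade_rate = 1.0 * exp(spec$effect_saccade_rate * z + eps[4]),
        change_prob = stats::plogis(stats::qlogis(c(0.45, 0.40)) + change_logit),
        coupling = c(coupling1, coupling2),
        decision_median = c(6.8, 8.2) * exp(0.2 * stats::rnorm(2)),
        second_median = 5.0 * exp(0.2 * stats::rnorm(1)),
        questionnaire_minutes = stats::runif(1, 65, 110),
        seed = substream_seed(spec$seed, "participant", k)
      )
      list(id = sprintf("P%03d", k), trait = traits[k], params = params)
    })
  })
}

# piecewise-constant renewal switching process evaluated on grid t:
# switch times have intervals min_gap + Exp(mean_gap), values drawn by rfun
switching_process <- function(t, duration, mean_gap, min_gap, rfun) {
  n_max <- ceiling(duration / min_gap) + 2L
  gaps <- min_gap + stats::rexp(n_max, 1 / mean_gap)
  times <- c(0, cumsum(gaps))
  times <- times[times < duration]
  vals <- rfun(length(times))
  idx <- findInterval(t, times)
  list(values = vals[idx], times = times, vals = vals)
}

# first-order recursive low-pass; a = exp(-dt/tau)
lowpass <- function(x, dt, tau) {
  a <- exp(-dt / tau)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive",
                           init = x[1]))
}

ou_noise <- function(n, dt, tau, sd) {
  a <- exp(-dt / tau)
  e <- stats::rnorm(n, sd = sd * sqrt(1 - a^2))
  as.numeric(stats::filter(e, a, method = "recursive"))
}

#' Generate a raw multimodal recording
#'
#' Simulates one recording (one odd-one-out round) for a participant:
#' a shared latent "target switch" renewal process drives near-instant gaze
#' saccades, smoothed reach-like hand trajectories and slow head rotations.
#' Gaze (nominal 200 Hz) carries a confidence channel with low-confidence
#' gaps and out-of-world-frame excursions; hand (100 Hz) has occasional
#' tracking dropouts (timestamp gaps); head (60 Hz) angles are reported on
#' the 0-360 degree convention. The participant's coupling parameter sets how
#' strongly hand and head follow the shared target rather than their own
#' independent processes, which controls the off-diagonal magnitude of the
#' downstream coordination matrix.
#'
#' @param params participant parameter list from [generate_cohort()].
#' @param duration recording length in seconds (>= 120 so that at least 60 s
#'   of valid data survives preprocessing).
#' @param seed integer seed for this recording.
#' @param round which task round (1 or 2); selects the round's coupling.
#' @param gaze_gap_rate low-confidence gaze gap events per minute.
#' @param low_conf_frac fraction of additional isolated gaze samples given
#'   confidence below 0.6.
#' @param hand_gap_rate hand tracking dropouts per minute.
#' @return a `raw_recording`: list of data frames `hand` (t, x, y, z),
#'   `gaze` (t, x, y, confidence), `head` (t, rx, ry, rz), with the planted
#'   saccade ground truth in `attr(, "saccade_times")`.
#' @export
generate_recording <- function(params, duration = 120, seed = 1L, round = 1L,
                               gaze_gap_rate = 2, low_conf_frac = 0.02,
                               hand_gap_rate = 1) {
  stop_if(!is.numeric(duration) || duration < 120,
          "duration must be >= 120 seconds")
  kappa <- params$coupling[min(round, length(params$coupling))]
  with_seed(seed, {
    t_gaze <- seq(0, duration, by = 1 / 200)
    t_hand <- seq(0, duration, by = 1 / 100)
    t_head <- seq(0, duration, by = 1 / 60)

    # shared latent target: one switch-time renewal process, independent
    # coordinates in the display frame
    gaps <- 0.4 + stats::rexp(ceiling(duration / 0.4) + 2L, 1 / 1.1)
    tgt_times <- c(0, cumsum(gaps))
    tgt_times <- tgt_times[tgt_times < duration]
    tgt_vals <- matrix(stats::runif(3 * length(tgt_times), 0.1, 0.9),
                       ncol = 3)
    tgt_at <- function(t, i) tgt_vals[findInterval(t, tgt_times), i]

    ## ---- gaze: fixation/saccade point process + drift ----
    g_amp <- min(1.2, max(0.25, 0.7 * params$gaze_speed_factor))
    # extra gaze-only saccades on top of target switches
    extra <- switching_process(t_gaze, duration,
                               mean_gap = 1 / max(params$saccade_rate, 1e-3),
                               min_gap = 0.15,
                               function(n) stats::runif(n, 0.1, 0.9))
    # gaze fixates a mixture stream: at any time the most recent event
    # (target switch or extra saccade) defines the fixation point
    ev_times <- c(tgt_times, extra$times)
    ev_x <- c(tgt_vals[, 1], extra$vals)
    ev_y <- c(tgt_vals[, 2], stats::runif(length(extra$times), 0.1, 0.9))
    ord <- order(ev_times)
    ev_times <- ev_times[ord]; ev_x <- ev_x[ord]; ev_y <- ev_y[ord]
    # enforce a minimum fixation dwell so planted saccades stay separable
    keep <- c(TRUE, diff(ev_times) > 0.12)
    ev_times <- ev_times[keep]; ev_x <- ev_x[keep]; ev_y <- ev_y[keep]
    idx <- findInterval(t_gaze, ev_times)
    idx[idx == 0] <- 1L
    fx <- 0.5 + g_amp * (ev_x[idx] - 0.5)
    fy <- 0.5 + g_amp * (ev_y[idx] - 0.5)
    gx <- pmin(0.995, pmax(0.005, fx + ou_noise(length(t_gaze), 1 / 200, 0.4,
                                                0.006 * g_amp)))
    gy <- pmin(0.995, pmax(0.005, fy + ou_noise(length(t_gaze), 1 / 200, 0.4,
                                                0.006 * g_amp)))
    conf <- stats::runif(length(t_gaze), 0.75, 1)
    # low-confidence gap events, half of them wandering out of frame
    n_gap <- stats::rpois(1, gaze_gap_rate * duration / 60)
    if (n_gap > 0) {
      starts <- stats::runif(n_gap, 0, duration)
      durs <- stats::rexp(n_gap, 1 / 0.8)
      for (i in seq_len(n_gap)) {
        in_gap <- t_gaze >= starts[i] & t_gaze <= starts[i] + durs[i]
        conf[in_gap] <- stats::runif(sum(in_gap), 0, 0.55)
        if (i %% 2 == 0) gx[in_gap] <- gx[in_gap] + 1.2  # outside world frame
      }
    }
    if (low_conf_frac > 0) {
      iso <- stats::runif(length(t_gaze)) < low_conf_frac
      conf[iso] <- stats::runif(sum(iso), 0, 0.55)
    }
    gaze <- data.frame(t = t_gaze, x = gx, y = gy, confidence = conf)

    ## ---- hand: smoothed reaches toward coupled target ----
    h_amp <- min(1.5, max(0.2, 0.8 * params$hand_speed_factor))
    own <- lapply(1:3, function(i)
      switching_process(t_hand, duration, mean_gap = 1.3, min_gap = 0.5,
                        function(n) stats::runif(n, 0.1, 0.9)))
    hand_xyz <- lapply(1:3, function(i) {
      mix <- kappa * tgt_at(t_hand, i) + (1 - kappa) * own[[i]]$values
      sm <- lowpass(lowpass(mix, 1 / 100, 0.22), 1 / 100, 0.22)
      0.5 + h_amp * (sm - 0.5) + ou_noise(length(t_hand), 1 / 100, 0.3,
                                          0.004 * h_amp)
    })
    hand <- data.frame(t = t_hand, x = hand_xyz[[1]], y = hand_xyz[[2]],
                       z = hand_xyz[[3]])
    n_hgap <- stats::rpois(1, hand_gap_rate * duration / 60)
    if (n_hgap > 0) {
      starts <- stats::runif(n_hgap, 2, duration - 2)
      for (s in starts) hand <- hand[hand$t < s | hand$t > s + 0.4, ]
    }

    ## ---- head: slow coupled rotations, 0-360 convention ----
    a_scale <- min(2, max(0.2, params$head_speed_factor))
    own_h <- lapply(1:3, function(i)
      switching_process(t_head, duration, mean_gap = 1.6, min_gap = 0.6,
                        function(n) stats::runif(n, 0.1, 0.9)))
    head_ang <- function(i, amp) {
      mix <- kappa * tgt_at(t_head, i) + (1 - kappa) * own_h[[i]]$values
      sm <- lowpass(mix, 1 / 60, 0.7)
      amp * a_scale * (sm - 0.5) * 2 +
        ou_noise(length(t_head), 1 / 60, 1.5, 0.8)
    }
    rx <- head_ang(1, 25); ry <- head_ang(2, 15); rz <- head_ang(3, 8)
    head <- data.frame(t = t_head,
                       rx = rx %% 360, ry = ry %% 360, rz = rz %% 360)

    structure(list(hand = hand, gaze = gaze, head = head,
                   duration = duration),
              class = "raw_recording",
              saccade_times = ev_times[ev_times > 0],
              coupling = kappa)
  })
}

#' Generate an odd-one-out trial log
#'
#' Round 1 has 12 trials, round 2 has 13. Each trial independently offers a
#' change opportunity with probability 1/2; when offered, the decision is
#' changed with the participant's per-round change probability. Decision
#' times are log-normal around participant/round-specific medians.
#'
#' @param params participant parameter list from [generate_cohort()].
#' @param seed integer seed.
#' @return data frame with columns `round`, `trial_index`,
#'   `time_first_decision`, `opportunity_offered`, `changed`,
#'   `time_second_decision` (`changed` and `time_second_decision` are `NA`
#'   when no opportunity was offered).
#' @export
generate_task_log <- function(params, seed = 1L) {
  p <- params$change_prob
  stop_if(any(p < 0 | p > 1), "change probabilities must be in [0, 1]")
  with_seed(seed, {
    logs <- lapply(1:2, function(r) {
      n <- c(12L, 13L)[r]
      opp <- stats::runif(n) < 0.5
      changed <- ifelse(opp, stats::runif(n) < p[r], NA)
      t1 <- stats::rlnorm(n, log(params$decision_median[r]), 0.35)
      t2 <- ifelse(opp, stats::rlnorm(n, log(params$second_median), 0.35), NA)
      data.frame(round = r, trial_index = seq_len(n),
                 time_first_decision = t1, opportunity_offered = opp,
                 changed = as.logical(changed), time_second_decision = t2)
    })
    do.call(rbind, logs)
  })
}

#' Generate a full synthetic study
#'
#' Convenience wrapper: cohort parameters, one recording per round per
#' participant, and a task log.
#'
#' @param spec a [cohort_spec()].
#' @param duration recording duration per round, seconds.
#' @param ... passed to [generate_recording()].
#' @return list with `spec`, `participants`; each participant gains
#'   `recordings` (list of two `raw_recording`s) and `task_log`.
#' @export
generate_study <- function(spec, duration = 120, ...) {
  cohort <- generate_cohort(spec)
  participants <- lapply(cohort, function(p) {
    p$recordings <- lapply(1:2, function(r)
      generate_recording(p$params, duration = duration,
                         seed = substream_seed(p$params$seed, "rec", r),
                         round = r, ...))
    p$task_log <- generate_task_log(
      p$params, seed = substream_seed(p$params$seed, "log"))
    p
  })
  list(spec = spec, participants = participants)
}

#' Write a synthetic study to disk
#'
#' One CSV per modality per participant per round, one task-log CSV per
#' participant, and a JSON manifest mapping participant ids to trait scores,
#' file paths and the master seed.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(study$participants, function(p) {
    files <- list()
    for (r in 1:2) {
      for (mod in c("hand", "gaze", "head")) {
        f <- file.path(dir, sprintf("%s_round%d_%s.csv", p$id, r, mod))
        utils::write.csv(p$recordings[[r]][[mod]], f, row.names = FALSE)
        files[[sprintf("round%d_%s", r, mod)]] <- f
      }
    }
    f <- file.path(dir, sprintf("%s_tasklog.csv", p$id))
    utils::write.csv(p$task_log, f, row.names = FALSE)
    files$task_log <- f
    list(id = p$id, trait = p$trait, files = files)
  })
  out <- list(seed = study$spec$seed, participants = manifest)
  jsonlite::write_json(out, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
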