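# tiny FNV-1a hash for config manifests (no external digest dependency)
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.double(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run: the cohort specification,
#' preprocessing thresholds, saccade thresholds, shrinkage, MDS and stepwise
#' settings, and the master seed. Round-trips losslessly through JSON.
#'
#' @param spec a [cohort_spec()].
#' @param duration recording duration per round, seconds.
#' @param min_confidence gaze confidence retention threshold.
#' @param max_gap resampling interpolation gap limit, seconds.
#' @param trim hand trim, seconds per end.
#' @param min_valid_seconds per-modality validity requirement, seconds.
#' @param velocity_threshold,accel_threshold,dist_threshold saccade
#'   detection thresholds.
#' @param epsilon correlation shrinkage toward the identity.
#' @param max_dims MDS dimensions screened by stepwise selection.
#' @param p_add,p_remove stepwise entry/removal thresholds.
#' @return a `run_config` list.
#' @export
run_config <- function(spec = cohort_spec(), duration = 120,
                       min_confidence = 0.6, max_gap = 0.5, trim = 2,
                       min_valid_seconds = 60,
                       velocity_threshold = 1.5, accel_threshold = 90,
                       dist_threshold = 0.005, epsilon = 1e-6,
                       max_dims = 10, p_add = 0.05, p_remove = 0.10) {
  cfg <- list(spec = spec, duration = duration,
              min_confidence = min_confidence, max_gap = max_gap,
              trim = trim, min_valid_seconds = min_valid_seconds,
              velocity_threshold = velocity_threshold,
              accel_threshold = accel_threshold,
              dist_threshold = dist_threshold, epsilon = epsilon,
              max_dims = max_dims, p_add = p_add, p_remove = p_remove)
  stop_if(any(!vapply(cfg[-1], function(v) is.finite(v) && v > 0, TRUE)),
          "all thresholds must be positive and finite")
  structure(cfg, class = "run_config")
}

#' Per-participant movement and task features for a synthetic study
#'
#' Runs preprocessing and feature extraction for every participant and
#' round: mean hand speed (10 Hz), mean head angular speed (10 Hz), mean
#' gaze speed and saccade rate (60 Hz), the per-round task measures, the
#' per-round coordination matrices, and the between-round Riemannian
#' stability distance. Modalities failing the validity rule are `NA` for
#' that participant.
#'
#' @param study a [generate_study()] result.
#' @param config a [run_config()].
#' @return list: `per_round` (list of two per-round feature data frames),
#'   `rd` (between-round RD per participant), `trait`, `ids`,
#'   `speeds` (per modality/round raw speed series for distribution
#'   building), `coord` (per-round lists of coordination matrices),
#'   `validity` (per-participant valid seconds).
#' @export
cohort_features <- function(study, config = run_config()) {
  ids <- vapply(study$participants, `[[`, "", "id")
  trait <- vapply(study$participants, `[[`, 0, "trait")
  n <- length(ids)
  feat <- lapply(1:2, function(r)
    data.frame(id = ids, trait = trait, ratio_changed = NA_real_,
               mean_time_first = NA_real_, mean_time_second = NA_real_,
               total_time = NA_real_, mean_head_velocity = NA_real_,
               mean_hand_velocity = NA_real_, mean_gaze_velocity = NA_real_,
               saccade_rate = NA_real_))
  rd <- rep(NA_real_, n)
  speeds <- list()
  coord <- list(vector("list", n), vector("list", n))
  validity <- data.frame(id = ids, gaze = 0, hand = 0, head = 0, joint = 0,
                         questionnaire_minutes =
                           vapply(study$participants, function(p)
                             p$params$questionnaire_minutes %||% 90, 0))
  for (k in seq_len(n)) {
    p <- study$participants[[k]]
    tm <- task_measures(p$task_log)
    cms <- list(NULL, NULL)
    for (r in 1:2) {
      feat[[r]]$ratio_changed[k] <- tm$ratio_changed[tm$round == r]
      feat[[r]]$mean_time_first[k] <- tm$mean_time_first[tm$round == r]
      feat[[r]]$mean_time_second[k] <- tm$mean_time_second[tm$round == r]
      feat[[r]]$total_time[k] <- tm$total_time[tm$round == r]
      prep <- tryCatch(
        preprocess_recording(p$recordings[[r]], max_gap = config$max_gap),
        error = function(e) NULL)
      if (is.null(prep)) next
      vs <- prep$valid_seconds
      if (r == 1) validity[k, c("gaze", "hand", "head", "joint")] <- vs
      if (vs["hand"] >= config$min_valid_seconds) {
        sp <- total_velocity(prep$hand10)
        feat[[r]]$mean_hand_velocity[k] <- mean_speed(sp)
        speeds[[paste0("hand_r", r, "_", ids[k])]] <- sp$speed[sp$valid]
      }
      if (vs["head"] >= config$min_valid_seconds) {
        sp <- total_velocity(prep$head10, angular = TRUE)
        feat[[r]]$mean_head_velocity[k] <- mean_speed(sp)
        speeds[[paste0("head_r", r, "_", ids[k])]] <- sp$speed[sp$valid]
      }
      if (vs["gaze"] >= config$min_valid_seconds) {
        sp <- total_velocity(prep$gaze60)
        feat[[r]]$mean_gaze_velocity[k] <- mean_speed(sp)
        speeds[[paste0("gaze_r", r, "_", ids[k])]] <- sp$speed[sp$valid]
        ev <- detect_saccades(prep$gaze60,
                              velocity_threshold = config$velocity_threshold,
                              accel_threshold = config$accel_threshold,
                              dist_threshold = config$dist_threshold)
        feat[[r]]$saccade_rate[k] <- saccade_rate(ev, vs["gaze"])
      }
      if (vs["joint"] >= config$min_valid_seconds) {
        cms[[r]] <- tryCatch(
          coordination_matrix(prep$aligned, epsilon = config$epsilon,
                              min_valid_seconds = config$min_valid_seconds),
          error = function(e) NULL)
        coord[[r]][[k]] <- cms[[r]]
      }
    }
    if (!is.null(cms[[1]]) && !is.null(cms[[2]])) {
      rd[k] <- round_stability(cms[[1]], cms[[2]])
    }
  }
  list(per_round = feat, rd = rd, trait = trait, ids = ids,
       speeds = speeds, coord = coord, validity = validity)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates generate, preprocess, featurize, distance, embed and
#' associate: simulates the cohort described by the config, extracts
#' per-participant features, builds per-modality velocity distributions on
#' shared Freedman-Diaconis edges and per-round coordination matrices,
#' assembles EMD and Riemannian distance matrices, embeds each with
#' classical MDS, runs constrained stepwise selection of a single MDS
#' coordinate against the trait score, and computes the direct trait
#' associations of the per-round features plus the between-round stability
#' distance. Fully deterministic given the config (which carries the master
#' seed).
#'
#' @param config a [run_config()].
#' @param output_dir optional directory; when given, result tables are
#'   written as CSV and the run manifest as JSON.
#' @return list: `mds_associations` (per representation x round: robust R^2,
#'   p, selected coordinate), `direct_associations` (per round, plus the
#'   between-round RD row), `round_time_comparison` (medians and rank-sum
#'   p), `exclusions`, `features`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), output_dir = NULL) {
  stop_if(!inherits(config, "run_config"), "config must be a run_config")
  study <- generate_study(config$spec, duration = config$duration)
  fx <- cohort_features(study, config)
  excl <- apply_exclusions(fx$validity,
                           min_valid_seconds = config$min_valid_seconds)

  # shared FD edges per modality, pooled over every recording of the cohort
  edges <- lapply(stats::setNames(nm = c("hand", "gaze", "head")),
                  function(mod) {
    pooled <- unlist(fx$speeds[startsWith(names(fx$speeds), mod)],
                     use.names = FALSE)
    if (length(pooled) >= 4) fd_bin_edges(pooled) else NULL
  })

  # distance matrices and MDS/stepwise per representation and round
  mds_rows <- list()
  for (mod in c("hand", "gaze", "head")) {
    for (r in 1:2) {
      key <- paste0(mod, "_r", r, "_")
      nm <- names(fx$speeds)[startsWith(names(fx$speeds), key)]
      if (length(nm) < 10 || is.null(edges[[mod]])) next
      items <- lapply(fx$speeds[nm], velocity_histogram,
                      edges = edges[[mod]], modality = mod)
      names(items) <- sub(key, "", nm)
      D <- pairwise_distances(items, "emd")
      emb <- mds_embed(D, max_dims = config$max_dims)
      y <- fx$trait[match(names(items), fx$ids)]
      sel <- stepwise_select(emb, y, p_add = config$p_add,
                             p_remove = config$p_remove,
                             max_coords = config$max_dims)
      mds_rows[[paste0(mod, "_round", r)]] <- data.frame(
        representation = mod, round = r, n = length(items),
        selected_coordinate = sel$selected,
        r_squared = if (is.null(sel$fit)) NA_real_ else sel$fit$r_squared,
        p_value = if (is.null(sel$fit)) NA_real_ else sel$fit$p_value)
    }
  }
  for (r in 1:2) {
    have <- which(!vapply(fx$coord[[r]], is.null, TRUE))
    if (length(have) >= 10) {
      items <- fx$coord[[r]][have]
      names(items) <- fx$ids[have]
      D <- pairwise_distances(items, "riemannian")
      emb <- mds_embed(D, max_dims = config$max_dims)
      sel <- stepwise_select(emb, fx$trait[have], p_add = config$p_add,
                             p_remove = config$p_remove,
                             max_coords = config$max_dims)
      mds_rows[[paste0("corr_round", r)]] <- data.frame(
        representation = "corr_matrix", round = r, n = length(items),
        selected_coordinate = sel$selected,
        r_squared = if (is.null(sel$fit)) NA_real_ else sel$fit$r_squared,
        p_value = if (is.null(sel$fit)) NA_real_ else sel$fit$p_value)
    }
  }
  mds_associations <- if (length(mds_rows)) do.call(rbind, mds_rows) else NULL

  direct <- lapply(1:2, function(r) {
    df <- fx$per_round[[r]]
    out <- direct_associations(
      df[setdiff(names(df), c("id", "trait"))], df$trait)
    out$round <- r
    out
  })
  ok_rd <- is.finite(fx$rd)
  if (sum(ok_rd) >= 3) {
    fit <- robust_fit(fx$rd[ok_rd], fx$trait[ok_rd])
    direct[[3]] <- data.frame(feature = "rd_between_rounds", n = fit$n,
                              rho = fit$rho, r_squared = fit$r_squared,
                              p_value = fit$p_value, round = NA_integer_)
  }
  direct_tab <- do.call(rbind, direct)
  rownames(direct_tab) <- NULL

  t1 <- unlist(lapply(study$participants, function(p)
    p$task_log$time_first_decision[p$task_log$round == 1]))
  t2 <- unlist(lapply(study$participants, function(p)
    p$task_log$time_first_decision[p$task_log$round == 2]))
  round_cmp <- list(median_round1 = stats::median(t1),
                    median_round2 = stats::median(t2),
                    p_value = compare_rounds(t1, t2))

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, force = TRUE)
  manifest <- list(config_hash = fnv1a(as.character(cfg_json)),
                   seed = config$spec$seed,
                   n_participants = config$spec$n_participants,
                   exclusions = excl$report,
                   multiple_testing_correction = "none",
                   negative_eig_note =
                     "MDS dimensions with negative eigenvalues truncated")

  result <- list(mds_associations = mds_associations,
                 direct_associations = direct_tab,
                 round_time_comparison = round_cmp,
                 exclusions = excl, features = fx, manifest = manifest)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(mds_associations))
      utils::write.csv(mds_associations,
                       file.path(output_dir, "mds_associations.csv"),
                       row.names = FALSE)
    utils::write.csv(direct_tab,
                     file.path(output_dir, "direct_associations.csv"),
                     row.names = FALSE)
    jsonlite::write_json(c(manifest, round_cmp),
                         file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}
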