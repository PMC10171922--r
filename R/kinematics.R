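#' Total-velocity (speed) series of a uniformly sampled stream
#'
#' Per-sample speed as the Euclidean norm of the per-channel velocities,
#' computed by central finite differences (one-sided at the ends) over the
#' uniform sample interval: the 3-D form for hand position and head rotation
#' channels, the 2-D form for gaze. Angle channels are differenced on the
#' circle (shortest arc) so sweeps across the +/-180 degree seam do not
#' produce spurious spikes. A speed sample adjacent to any invalid input
#' sample is itself invalid.
#'
#' @param stream data frame with `t`, value channels, optional `valid`.
#' @param angular treat channels as degrees on the circle (head rotations);
#'   result is then in deg/s.
#' @return data frame `t`, `speed`, `valid`.
#' @export
total_velocity <- function(stream, angular = FALSE) {
  chans <- setdiff(names(stream), c("t", "valid"))
  n <- nrow(stream)
  stop_if(n < 2, "need at least 2 samples")
  dts <- diff(stream$t)
  dt <- stats::median(dts)
  stop_if(any(abs(dts - dt) > 1e-6 * max(dt, 1)),
          "stream is not uniformly sampled")
  sq <- 0
  for (ch in chans) {
    x <- stream[[ch]]
    d <- if (angular) wrap180(diff(x)) else diff(x)   # step i -> i+1
    v <- c(d[1], (d[-1] + d[-(n - 1)]) / 2, d[n - 1]) / dt
    sq <- sq + v^2
  }
  valid <- stream$valid %||% rep(TRUE, n)
  vfin <- valid & c(valid[-1], TRUE) & c(TRUE, valid[-n])
  data.frame(t = stream$t, speed = sqrt(sq), valid = vfin)
}

#' Freedman-Diaconis bin edges for pooled speeds
#'
#' Bin width `h = 2 * IQR * n^(-1/3)` computed on the speeds pooled across
#' every recording of one modality, so that all recordings share identical
#' edges. Quartiles use the midpoint (Hazen) linear-interpolation convention
#' (`quantile(..., type = 5)`). Edges run from 0 in steps of `h`; the last
#' edge is at or beyond the pooled maximum. With zero IQR (heavily tied
#' data) the width falls back to the Scott-like `3.49 * sd * n^(-1/3)`, and
#' the fallback is recorded in the result's `rule` attribute.
#'
#' @param pooled numeric vector of pooled speeds (n >= 4).
#' @return numeric vector of bin edges with attribute `rule`.
#' @export
fd_bin_edges <- function(pooled) {
  pooled <- pooled[is.finite(pooled)]
  n <- length(pooled)
  stop_if(n < 4, "need at least 4 pooled values")
  iqr <- diff(stats::quantile(pooled, c(0.25, 0.75), type = 5, names = FALSE))
  rule <- "freedman-diaconis"
  h <- 2 * iqr * n^(-1 / 3)
  if (h <= 0) {
    rule <- "scott-fallback"
    h <- 3.49 * stats::sd(pooled) * n^(-1 / 3)
  }
  if (h <= 0) h <- max(abs(pooled[1]), 1) * 1e-6  # fully degenerate input
  top <- max(pooled)
  edges <- seq(0, top, by = h)
  if (edges[length(edges)] < top) edges <- c(edges, edges[length(edges)] + h)
  if (length(edges) < 2) edges <- c(0, h)
  structure(edges, rule = rule, h = h)
}

#' Histogram/CDF representation of a speed series
#'
#' Empirical distribution of the valid speed samples on shared bin edges:
#' probability mass per bin (sums to 1) and the empirical CDF evaluated at
#' the edges (piecewise linear in between, i.e. uniform density within each
#' bin). Speeds beyond the final edge are counted in the last bin.
#'
#' @param speed data frame from [total_velocity()] (or numeric vector).
#' @param edges shared edges from [fd_bin_edges()].
#' @param modality tag: `"hand"`, `"gaze"` or `"head"`.
#' @return a `velocity_distribution`: list with `edges`, `pdf`, `cdf`,
#'   `n_samples`, `modality`.
#' @export
velocity_histogram <- function(speed, edges, modality = "unknown") {
  s <- if (is.data.frame(speed)) speed$speed[speed$valid] else speed
  s <- s[is.finite(s)]
  stop_if(length(s) == 0, "no valid speed samples")
  s <- pmin(pmax(s, edges[1]), edges[length(edges)])
  counts <- graphics::hist(s, breaks = edges, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  pdf <- counts / sum(counts)
  structure(list(edges = as.numeric(edges), pdf = pdf,
                 cdf = c(0, cumsum(pdf)), n_samples = length(s),
                 modality = modality),
            class = "velocity_distribution")
}

#' Detect saccades in a 60 Hz gaze stream
#'
#' Candidate saccades are maximal runs of valid samples whose speed exceeds
#' the velocity threshold; runs separated by a single sub-threshold sample
#' are merged. A candidate is kept only if its peak acceleration (first
#' difference of speed over the sample interval) exceeds `accel_threshold`
#' and the path distance travelled during the event exceeds
#' `dist_threshold`. The velocity threshold is not fixed by convention and
#' is exposed as configuration; the default of 1.5 a.u./s sits well above
#' simulated fixational drift (about 0.05 a.u./s) and well below single-frame
#' saccadic jumps.
#'
#' @param gaze data frame `t`, `x`, `y`, optional `valid`, uniformly sampled
#'   (nominally 60 Hz).
#' @param velocity_threshold speed threshold, a.u./s.
#' @param accel_threshold peak-acceleration threshold, a.u./s^2.
#' @param dist_threshold minimum path distance, a.u.
#' @return data frame of events: `onset`, `offset`, `peak_velocity`,
#'   `peak_acceleration`, `distance`.
#' @export
detect_saccades <- function(gaze, velocity_threshold = 1.5,
                            accel_threshold = 90, dist_threshold = 0.005) {
  stop_if(nrow(gaze) < 3, "gaze series shorter than 3 samples")
  sp <- total_velocity(gaze[c("t", "x", "y",
                              intersect("valid", names(gaze)))])
  dt <- stats::median(diff(gaze$t))
  acc <- c(0, diff(sp$speed)) / dt
  step <- sqrt(diff(gaze$x)^2 + diff(gaze$y)^2)  # displacement i -> i+1
  above <- sp$speed > velocity_threshold & sp$valid
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) > 1) {  # merge runs separated by at most one sample
    merged <- runs[1, , drop = FALSE]
    for (k in 2:nrow(runs)) {
      if (runs[k, 1] - merged[nrow(merged), 2] <= 2) {
        merged[nrow(merged), 2] <- runs[k, 2]
      } else merged <- rbind(merged, runs[k, ])
    }
    runs <- merged
  }
  n <- nrow(gaze)
  nr <- nrow(runs)
  if (nr == 0) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      peak_velocity = numeric(0),
                      peak_acceleration = numeric(0), distance = numeric(0)))
  }
  cstep <- c(0, cumsum(step))  # cstep[i] = path length up to sample i
  i0 <- runs[, 1]; i1 <- runs[, 2]
  dist <- cstep[pmin(i1 + 1, n)] - cstep[pmax(i0 - 1, 1)]
  pk_acc <- vapply(seq_len(nr), function(k)
    max(abs(acc[i0[k]:min(i1[k] + 1, n)])), 0)
  pk_vel <- vapply(seq_len(nr), function(k) max(sp$speed[i0[k]:i1[k]]), 0)
  keep <- pk_acc > accel_threshold & dist > dist_threshold
  data.frame(onset = gaze$t[i0[keep]], offset = gaze$t[i1[keep]],
             peak_velocity = pk_vel[keep], peak_acceleration = pk_acc[keep],
             distance = dist[keep])
}

#' Saccade rate over the valid recording time
#'
#' @param events data frame from [detect_saccades()].
#' @param valid_seconds seconds of valid gaze data.
#' @return saccades per second.
#' @export
saccade_rate <- function(events, valid_seconds) {
  stop_if(!is.finite(valid_seconds) || valid_seconds <= 0,
          "valid duration must be positive")
  nrow(events) / valid_seconds
}

#' Mean speed over valid samples
#'
#' @param speed data frame from [total_velocity()] or numeric vector.
#' @return mean of the valid speed samples.
#' @export
mean_speed <- function(speed) {
  s <- if (is.data.frame(speed)) speed$speed[speed$valid] else speed
  stop_if(length(s) == 0, "no valid samples")
  mean(s)
}

#' Per-round task measures from a trial log
#'
#' For each round: the ratio of changed decisions (changes divided by change
#' opportunities; `NA` when the round offered none), mean first- and
#' second-decision times, and total decision time.
#'
#' @param trial_log data frame from [generate_task_log()] (columns `round`,
#'   `opportunity_offered`, `changed`, `time_first_decision`,
#'   `time_second_decision`).
#' @return data frame with one row per round: `round`, `ratio_changed`,
#'   `mean_time_first`, `mean_time_second`, `total_time`, `n_opportunities`.
#' @export
task_measures <- function(trial_log) {
  need <- c("round", "opportunity_offered", "changed",
            "time_first_decision", "time_second_decision")
  stop_if(!all(need %in% names(trial_log)), "malformed trial log")
  do.call(rbind, lapply(sort(unique(trial_log$round)), function(r) {
    tl <- trial_log[trial_log$round == r, ]
    opp <- sum(tl$opportunity_offered)
    data.frame(
      round = r,
      ratio_changed = if (opp == 0) NA_real_ else
        sum(tl$changed[tl$opportunity_offered]) / opp,
      mean_time_first = mean(tl$time_first_decision),
      mean_time_second = if (opp == 0) NA_real_ else
        mean(tl$time_second_decision[tl$opportunity_offered]),
      total_time = sum(tl$time_first_decision) +
        sum(tl$time_second_decision[tl$opportunity_offered]),
      n_opportunities = opp)
  }))
}
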