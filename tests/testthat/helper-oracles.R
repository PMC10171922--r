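# Independent oracles used across the suite. Each is deliberately written
# against a different formulation than the implementation it checks.

# Exact 1-D optimal transport cost between weighted discrete distributions.
# For a convex ground cost on the line the monotone (sorted) coupling is the
# linear-programming optimum, so greedy mass matching of the sorted supports
# computes the exact minimal-cost transport.
transport_cost_1d <- function(x, wx, y, wy) {
  ox <- order(x); oy <- order(y)
  x <- x[ox]; wx <- wx[ox] / sum(wx)
  y <- y[oy]; wy <- wy[oy] / sum(wy)
  i <- 1; j <- 1; cost <- 0
  while (i <= length(x) && j <= length(y)) {
    m <- min(wx[i], wy[j])
    cost <- cost + m * abs(x[i] - y[j])
    wx[i] <- wx[i] - m
    wy[j] <- wy[j] - m
    if (wx[i] <= 1e-15) i <- i + 1
    if (wy[j] <= 1e-15) j <- j + 1
  }
  cost
}

# Exact two-sided rank-sum p-value by enumeration of all assignments.
ranksum_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pooled), n)
  stats_all <- apply(idx, 2, function(ii) sum(rank(pooled)[ii]))
  obs <- sum(rank(pooled)[seq_len(n)])
  mu <- mean(stats_all)
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-12)
}

# Uniform sample stream builders used by preprocessing/kinematics tests.
make_stream <- function(t, ...) data.frame(t = t, ...)

make_gaze <- function(t, x, y, confidence = rep(1, length(t))) {
  data.frame(t = t, x = x, y = y, confidence = confidence)
}

# An aligned_recording built directly from an 8-column matrix (bypasses
# preprocessing; for similarity-stage tests).
make_aligned <- function(X, rate = 10, valid = rep(TRUE, nrow(X))) {
  chans <- c("hand_x", "hand_y", "hand_z", "gaze_x", "gaze_y",
             "head_rx", "head_ry", "head_rz")
  df <- as.data.frame(X)
  names(df) <- chans
  df <- cbind(t = seq_len(nrow(df)) / rate, df)
  df$valid <- valid
  class(df) <- c("aligned_recording", "data.frame")
  attr(df, "rate") <- rate
  df
}

# random symmetric positive-definite matrix
random_spd <- function(d) {
  A <- matrix(rnorm(d * d), d)
  crossprod(A) + diag(d) * 0.5
}

# velocity_distribution straight from a numeric sample and edges
vd_of <- function(x, edges, modality = "hand") {
  velocity_histogram(x, edges, modality = modality)
}
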