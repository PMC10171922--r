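# Exact integral of |f| for a function piecewise linear between grid points,
# given endpoint values d (sign changes handled analytically).
integrate_abs_pl <- function(x, d) {
  a <- d[-length(d)]; b <- d[-1]; h <- diff(x)
  cross <- a * b < 0
  seg <- ifelse(cross,
                (a^2 + b^2) / (2 * (abs(a) + abs(b))) * h,
                (abs(a) + abs(b)) / 2 * h)
  sum(seg)
}

#' Earth mover's distance between two velocity distributions
#'
#' One-dimensional EMD via its closed form: the integral of the absolute
#' difference of the two cumulative distribution functions. Both CDFs are
#' interpolated onto the union of their bin-edge grids (they are piecewise
#' linear between edges, since histogram bins carry uniform density) and the
#' absolute difference is integrated exactly, with sign-change points inside
#' a segment handled analytically. The result is in the units of the
#' support (a.u./s for hand and gaze, deg/s for head).
#'
#' @param dist_a,dist_b `velocity_distribution` objects of one modality.
#' @return nonnegative scalar distance.
#' @export
emd <- function(dist_a, dist_b) {
  stop_if(!inherits(dist_a, "velocity_distribution") ||
            !inherits(dist_b, "velocity_distribution"),
          "emd() expects two velocity_distribution objects")
  stop_if(!identical(dist_a$modality, dist_b$modality),
          "cannot compare distributions of different modalities (",
          dist_a$modality, " vs ", dist_b$modality, ")")
  grid <- sort(unique(c(dist_a$edges, dist_b$edges)))
  f <- function(d) stats::approx(d$edges, d$cdf, xout = grid,
                                 yleft = 0, yright = 1)$y
  integrate_abs_pl(grid, f(dist_a) - f(dist_b))
}

#' Earth mover's distance between two weighted discrete samples
#'
#' The same closed form applied to step (empirical) CDFs: on the union of
#' the atom locations, the integral reduces to the sum of
#' `|CDF1 - CDF2| * gap` over consecutive atoms, which equals the minimal
#' transport cost exactly.
#'
#' @param x,y atom locations.
#' @param wx,wy nonnegative weights (normalized internally; default uniform).
#' @return nonnegative scalar distance.
#' @export
emd_samples <- function(x, y, wx = NULL, wy = NULL) {
  wx <- wx %||% rep(1, length(x)); wy <- wy %||% rep(1, length(y))
  wx <- wx / sum(wx); wy <- wy / sum(wy)
  z <- sort(unique(c(x, y)))
  F1 <- vapply(z, function(v) sum(wx[x <= v]), 0)
  F2 <- vapply(z, function(v) sum(wy[y <= v]), 0)
  sum(abs(F1 - F2)[-length(z)] * diff(z))
}

#' Coordination matrix of an aligned recording
#'
#' The 8x8 matrix of pairwise Pearson correlations between the aligned
#' channels (hand x, y, z; gaze x, y; head rx, ry, rz), computed over the
#' jointly valid samples only. The matrix is symmetrised and shrunk toward
#' the identity, `(1 - eps) C + eps I`, to guarantee positive definiteness
#' for the Riemannian geometry downstream.
#'
#' @param aligned an `aligned_recording` from [align_streams()].
#' @param epsilon shrinkage weight toward the identity.
#' @param min_valid_seconds minimum jointly valid time required.
#' @return a `coordination_matrix` (8x8 numeric matrix with attributes
#'   `n_valid` and `epsilon`).
#' @export
coordination_matrix <- function(aligned, epsilon = 1e-6,
                                min_valid_seconds = 60) {
  chans <- c("hand_x", "hand_y", "hand_z", "gaze_x", "gaze_y",
             "head_rx", "head_ry", "head_rz")
  X <- as.matrix(as.data.frame(aligned)[aligned$valid, chans])
  rate <- attr(aligned, "rate") %||% 10
  stop_if(nrow(X) / rate < min_valid_seconds,
          "fewer than ", min_valid_seconds, " s of jointly valid samples")
  sds <- apply(X, 2, stats::sd)
  stop_if(any(sds == 0), "constant channel(s): ",
          paste(chans[sds == 0], collapse = ", "))
  C <- stats::cor(X)
  C <- (C + t(C)) / 2
  C <- (1 - epsilon) * C + epsilon * diag(ncol(C))
  structure(C, class = c("coordination_matrix", class(C)),
            n_valid = nrow(X), epsilon = epsilon)
}

#' Affine-invariant Riemannian distance between correlation matrices
#'
#' `RD(C1, C2) = sqrt(sum_n log^2 lambda_n)` where `lambda_n` are the
#' eigenvalues of `C1^-1 C2` (equivalently of `C1^-1/2 C2 C1^-1/2`). This is
#' the standard affine-invariant metric on symmetric positive-definite
#' matrices: symmetric in its arguments and invariant under congruence
#' `C -> A C A'` for invertible `A`. The squared variant is available via
#' `squared = TRUE`.
#'
#' @param c1,c2 symmetric positive-definite matrices of equal size.
#' @param squared return the squared distance instead.
#' @return nonnegative scalar.
#' @export
riemannian_distance <- function(c1, c2, squared = FALSE) {
  c1 <- unclass(c1); c2 <- unclass(c2)
  stop_if(!all(dim(c1) == dim(c2)), "matrices must have equal dimensions")
  for (m in list(c1, c2)) {
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    stop_if(min(ev) <= 0,
            "matrix is not positive definite; regularise it first ",
            "(e.g. shrinkage toward the identity)")
  }
  lam <- Re(eigen(solve(c1, c2), only.values = TRUE)$values)
  d2 <- sum(log(lam)^2)
  if (squared) d2 else sqrt(d2)
}

#' Pairwise distance matrix over a list of representations
#'
#' Assembles the full symmetric distance matrix between recordings
#' represented either as `velocity_distribution`s (metric `"emd"`) or as
#' `coordination_matrix`/SPD matrices (metric `"riemannian"`). Entries are
#' computed in fixed row-major order from pure functions, so the result does
#' not depend on evaluation order.
#'
#' @param items named list of representations of one common type.
#' @param metric `"emd"` or `"riemannian"`.
#' @return a `distance_matrix`: symmetric nonnegative matrix with zero
#'   diagonal and dimnames from `names(items)`.
#' @export
pairwise_distances <- function(items, metric = c("emd", "riemannian")) {
  metric <- match.arg(metric)
  stop_if(length(items) < 2, "need at least 2 items")
  is_vd <- vapply(items, inherits, TRUE, what = "velocity_distribution")
  stop_if(metric == "emd" && !all(is_vd),
          "metric 'emd' requires velocity_distribution items")
  stop_if(metric == "riemannian" && any(is_vd),
          "metric 'riemannian' requires matrix items")
  fun <- if (metric == "emd") emd else riemannian_distance
  n <- length(items)
  D <- matrix(0, n, n,
              dimnames = list(names(items), names(items)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- fun(items[[i]], items[[j]])
    }
  }
  structure(D, class = c("distance_matrix", class(D)), metric = metric)
}
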