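#' Classical (Torgerson) MDS embedding of a distance matrix
#'
#' Double-centres `-D^2 / 2`, eigendecomposes, and keeps up to `max_dims`
#' dimensions with positive eigenvalues, ordered by decreasing explained
#' variability. For non-Euclidean inputs (EMD and Riemannian distance
#' matrices need not be Euclidean-embeddable) dimensions with negative
#' eigenvalues are truncated and their mass is reported in
#' `negative_eig_mass`. Coordinate signs are fixed deterministically: in
#' each dimension the largest-magnitude loading is positive.
#'
#' @param d symmetric, zero-diagonal distance matrix.
#' @param max_dims maximum number of dimensions to keep.
#' @return an `mds_embedding`: list with `points` (items x dims), `eig`
#'   (full spectrum), `ids`, `negative_eig_mass`.
#' @export
mds_embed <- function(d, max_dims = 10) {
  d <- unclass(d)
  stop_if(!isSymmetric(unname(d), tol = 1e-8), "distance matrix must be symmetric")
  stop_if(any(abs(diag(d)) > 1e-12), "distance matrix must have zero diagonal")
  n <- nrow(d)
  k <- min(max_dims, n - 1)
  fit <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1)
  keep <- which(fit$eig[seq_len(ncol(pts))] > 1e-10 * max(abs(fit$eig)))
  pts <- pts[, keep, drop = FALSE]
  for (j in seq_len(ncol(pts))) {
    if (pts[which.max(abs(pts[, j]))[1], j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("x", seq_len(ncol(pts)))
  rownames(pts) <- rownames(d)
  structure(list(points = pts, eig = fit$eig,
                 ids = rownames(d) %||% as.character(seq_len(n)),
                 negative_eig_mass = sum(abs(fit$eig[fit$eig < 0])) /
                   sum(abs(fit$eig))),
            class = "mds_embedding")
}

# residual sum of squares of OLS with intercept
.rss <- function(Xmat, y) {
  fit <- stats::lm.fit(cbind(1, Xmat), y)
  sum(fit$residuals^2)
}

#' Constrained stepwise selection of an MDS coordinate
#'
#' Stepwise linear regression of the trait response on the first
#' `max_coords` MDS coordinates: at each step the best absent term is added
#' if its partial F-test p-value is at most `p_add`; when nothing can be
#' added, the worst present term is removed if its F-test p-value is at
#' least `p_remove`; the constant term is never removed. The procedure stops
#' when no term can be added or removed. To guard against overfitting of
#' stepwise search, a model is *accepted* only when exactly one coordinate
#' survives; that surviving coordinate is then re-fit with robust
#' regression ([robust_fit()]).
#'
#' @param embedding an `mds_embedding`, or a numeric matrix of coordinates.
#' @param response trait scores aligned with the embedding's rows.
#' @param p_add,p_remove entry and removal p-value thresholds.
#' @param max_coords number of leading coordinates screened.
#' @return list: `in_model` (indices of coordinates in the final stepwise
#'   model), `selected` (the accepted single coordinate, or `NA`), `fit`
#'   (the [robust_fit()] result for the accepted coordinate, or `NULL`).
#' @export
stepwise_select <- function(embedding, response, p_add = 0.05,
                            p_remove = 0.10, max_coords = 10) {
  X <- if (inherits(embedding, "mds_embedding")) embedding$points else
    as.matrix(embedding)
  n <- length(response)
  stop_if(nrow(X) != n, "embedding and response lengths differ")
  stop_if(n < 10, "need at least 10 observations")
  X <- X[, seq_len(min(max_coords, ncol(X))), drop = FALSE]
  p <- ncol(X)
  if (stats::sd(response) == 0) {
    return(list(in_model = integer(0), selected = NA_integer_, fit = NULL))
  }
  S <- integer(0)
  for (iter in 1:50) {
    changed <- FALSE
    # addition step
    cand <- setdiff(seq_len(p), S)
    if (length(cand) > 0) {
      rss0 <- .rss(X[, S, drop = FALSE], response)
      pvals <- vapply(cand, function(j) {
        rss1 <- .rss(X[, c(S, j), drop = FALSE], response)
        df2 <- n - length(S) - 2
        f <- (rss0 - rss1) / (rss1 / df2)
        stats::pf(f, 1, df2, lower.tail = FALSE)
      }, 0)
      if (min(pvals) <= p_add) {
        S <- c(S, cand[which.min(pvals)])
        changed <- TRUE
      }
    }
    # removal step (only when nothing could be added)
    if (!changed && length(S) > 0) {
      rss1 <- .rss(X[, S, drop = FALSE], response)
      pvals <- vapply(S, function(j) {
        rss0 <- .rss(X[, setdiff(S, j), drop = FALSE], response)
        df2 <- n - length(S) - 1
        f <- (rss0 - rss1) / (rss1 / df2)
        stats::pf(f, 1, df2, lower.tail = FALSE)
      }, 0)
      if (max(pvals) >= p_remove) {
        S <- setdiff(S, S[which.max(pvals)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  selected <- if (length(S) == 1) S else NA_integer_
  fit <- if (!is.na(selected)) robust_fit(X[, selected], response) else NULL
  list(in_model = sort(S), selected = selected, fit = fit)
}

#' Robust simple regression with Tukey bisquare weights
#'
#' Iteratively reweighted least squares with the redescending bisquare
#' weight function (tuning constant 4.685, the conventional 95%-efficiency
#' value), via `MASS::rlm`. The coefficient of determination uses the final
#' robust weights: `R^2 = 1 - SSE_w / SST_w` with the weighted mean in the
#' total sum of squares. The p-value tests the robust model against the
#' constant model: the F statistic is the squared Wald statistic of the
#' slope over its robust standard error, referred to F(1, n - 2) (the
#' conventional inference for M-estimated regression; a weighted
#' residual-sum-of-squares F would be anticonservative because the weights
#' are chosen from the same data). The Pearson correlation is reported on
#' the raw (unweighted) pairs.
#'
#' @param x predictor (non-constant).
#' @param y response.
#' @param tuning bisquare tuning constant.
#' @return list: `rho`, `r_squared`, `p_value`, `slope`, `intercept`, `n`.
#' @export
robust_fit <- function(x, y, tuning = 4.685) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stop_if(n < 3, "need at least 3 complete observations")
  stop_if(stats::sd(x) == 0, "predictor is constant")
  rho <- stats::cor(x, y)
  ols <- stats::lm.fit(cbind(1, x), y)
  if (sum(ols$residuals^2) <= 1e-12 * sum((y - mean(y))^2) ||
      stats::sd(y) == 0) {
    # exact linear relation: robust IRLS has a zero scale, return the limit
    return(list(rho = rho, r_squared = 1,
                p_value = .Machine$double.xmin,
                slope = unname(ols$coefficients[2]),
                intercept = unname(ols$coefficients[1]), n = n))
  }
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = tuning,
                   maxit = 100)
  w <- fit$w
  res <- stats::residuals(fit)
  ybar_w <- sum(w * y) / sum(w)
  sse <- sum(w * res^2)
  sst <- sum(w * (y - ybar_w)^2)
  r2 <- max(0, min(1, 1 - sse / sst))
  tval <- summary(fit)$coefficients[2, "t value"]
  p <- stats::pf(tval^2, 1, n - 2, lower.tail = FALSE)
  list(rho = rho, r_squared = r2, p_value = max(p, .Machine$double.xmin),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = n)
}

#' Trait associations of per-participant features
#'
#' For each feature column, the Pearson correlation with the trait score and
#' the robust-regression R^2 and F-test p-value (trait as the response),
#' mirroring the direct-measure layout of the study's result tables.
#' Features with fewer than 3 complete pairs or zero variance are skipped
#' with a warning. No multiple-testing correction is applied across
#' features; consumers see the raw per-feature p-values.
#'
#' @param features data frame of per-participant features (one row per
#'   participant).
#' @param trait trait scores aligned with `features` rows.
#' @return data frame: `feature`, `n`, `rho`, `r_squared`, `p_value`.
#' @export
direct_associations <- function(features, trait) {
  rows <- lapply(names(features), function(fname) {
    x <- features[[fname]]
    ok <- is.finite(x) & is.finite(trait)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0) {
      warning("feature '", fname, "' skipped (missing or constant)")
      return(NULL)
    }
    fit <- robust_fit(x[ok], trait[ok])
    data.frame(feature = fname, n = fit$n, rho = fit$rho,
               r_squared = fit$r_squared, p_value = fit$p_value)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Rank-sum comparison of decision times between rounds
#'
#' Two-sided Wilcoxon-Mann-Whitney rank-sum test; exact enumeration for
#' small tie-free samples, tie-corrected normal approximation otherwise
#' (the behaviour of [stats::wilcox.test()]).
#'
#' @param times_round1,times_round2 non-empty numeric samples.
#' @return two-sided p-value.
#' @export
compare_rounds <- function(times_round1, times_round2) {
  stop_if(length(times_round1) == 0 || length(times_round2) == 0,
          "both samples must be non-empty")
  suppressWarnings(
    stats::wilcox.test(times_round1, times_round2)$p.value)
}

#' Between-round coordination stability
#'
#' Riemannian distance between one participant's coordination matrices from
#' the two task rounds; small values mean the cross-channel coordination
#' pattern was stable across rounds.
#'
#' @param c_round1,c_round2 `coordination_matrix` objects.
#' @return nonnegative scalar.
#' @export
round_stability <- function(c_round1, c_round2) {
  riemannian_distance(c_round1, c_round2)
}
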