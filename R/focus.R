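# Focus-surface interpolation and focus scoring.
#
# Best-focus height varies smoothly across a mounted slide; a third-degree
# polynomial surface fitted to a small set of manually focused positions
# interpolates focus for every spot, and a per-pass global offset tracked on
# invariant features compensates stage drift during acquisition.

#' Evaluate the cubic focus surface
#'
#' `z(x, y) = sum_{i=0}^{3} sum_{j=0}^{3} a_ij x^i y^j`, with `a_ij` stored
#' as `coeffs[i + 1, j + 1]`.
#'
#' @param coeffs 4x4 coefficient matrix.
#' @param x,y coordinates (normalized slide coordinates in `[-1, 1]`).
#' @return vector of surface heights.
#' @export
eval_focus_surface <- function(coeffs, x, y) {
  coeffs <- as.matrix(coeffs)
  if (!all(dim(coeffs) == c(4L, 4L))) stopf("coeffs must be 4x4")
  z <- numeric(length(x))
  for (i in 0:3)
    for (j in 0:3)
      z <- z + coeffs[i + 1, j + 1] * x^i * y^j
  z
}

focus_design_matrix <- function(x, y) {
  out <- matrix(0, length(x), 16L)
  k <- 0L
  for (i in 0:3)
    for (j in 0:3) {
      k <- k + 1L
      out[, k] <- x^i * y^j
    }
  out
}

ls_focus_fit <- function(x, y, z) {
  X <- focus_design_matrix(x, y)
  beta <- qr.coef(qr(X), z)
  beta[!is.finite(beta)] <- 0
  matrix(beta, 4L, 4L, byrow = TRUE)
}

#' Fit the cubic focus surface with RANSAC outlier rejection
#'
#' Fits `z = sum a_ij x^i y^j` to manually determined focus positions.
#' Coordinates are rescaled internally to `[-1, 1]` (over their observed
#' range) for numerical conditioning of the degree-3 cross terms. A RANSAC
#' loop (minimum sample 16 points, the number of coefficients) guards
#' against gross outliers: the consensus model with the most inliers wins
#' and the final surface is the least-squares fit on its inliers.
#'
#' The inlier threshold defaults to 3 times a robust (MAD-based) noise
#' estimate taken from the best minimum-sample model in a least-median-of-
#' squares sense, with a small floor so that noiseless input does not
#' collapse the threshold to zero. (A pilot full fit cannot provide the
#' scale here: 16 coefficients against 45 points are flexible enough to
#' absorb gross outliers, inflating a pilot-based threshold until nothing
#' is rejected.)
#'
#' @param points data.frame or matrix with columns `x`, `y`, `z`.
#' @param threshold absolute inlier residual threshold (um); `NULL` = auto.
#' @param n_iter RANSAC iterations.
#' @param min_inliers minimum consensus size (>= 16).
#' @param seed RNG seed for the sampling loop.
#' @return object of class `focus_surface`: `coeffs` (4x4, in the rescaled
#'   frame), `inlier` mask, `threshold`, and the `x_range`/`y_range` used
#'   for rescaling. Evaluate with [predict.focus_surface()].
#' @export
fit_focus_surface <- function(points, threshold = NULL, n_iter = 2000L,
                              min_inliers = 16L, seed = 1L) {
  points <- as.data.frame(points)
  n <- nrow(points)
  if (n < 16L) stopf("at least 16 points are needed to fit 16 coefficients")
  if (min_inliers < 16L) stopf("min_inliers must be >= 16")
  if (any(!is.finite(points$x)) || any(!is.finite(points$y)) ||
      any(!is.finite(points$z)))
    stopf("focus points must be finite")
  xr <- range(points$x); yr <- range(points$y)
  resc <- function(v, r) if (diff(r) > 0) 2 * (v - r[1]) / diff(r) - 1 else v * 0
  x <- resc(points$x, xr)
  y <- resc(points$y, yr)
  z <- points$z

  # minimum-sample search. The residual scale comes from the least-median-
  # of-squares candidate (robust to <50% corruption); candidates are then
  # re-scored by inlier count at that threshold, which prefers models whose
  # support spans the whole design over ones that bend to absorb a
  # high-leverage outlier.
  resids <- matrix(NA_real_, n, n_iter)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      idx <- sample.int(n, 16L)
      cf <- ls_focus_fit(x[idx], y[idx], z[idx])
      resids[, it] <- abs(z - eval_focus_surface(cf, x, y))
    }
  })
  meds <- apply(resids, 2, median)
  auto <- is.null(threshold)
  floor_thr <- 1e-6 * max(1, max(abs(z)))
  if (auto) {
    # LMedS scale with the standard small-sample correction
    sigma_hat <- 1.4826 * (1 + 5 / (n - 16)) * min(meds)
    threshold <- max(3 * sigma_hat, floor_thr)
  }
  threshold0 <- threshold
  counts <- colSums(resids <= threshold)
  rss <- colSums((resids * (resids <= threshold))^2)
  best_it <- order(-counts, rss)[1]
  best_inliers <- resids[, best_it] <= threshold
  # iterative refinement: a minimum-sample model understates the residual
  # scale, so refit on the consensus set, re-estimate the robust scale from
  # the full fit, and re-select until the inlier set is stable
  coeffs <- NULL
  for (it in 1:20) {
    if (sum(best_inliers) < min_inliers)
      stopf("RANSAC found no consensus set of >= %d inliers", min_inliers)
    coeffs <- ls_focus_fit(x[best_inliers], y[best_inliers], z[best_inliers])
    r <- abs(z - eval_focus_surface(coeffs, x, y))
    if (auto) {
      # residuals of a 16-parameter fit on n points understate the noise
      # by ~sqrt((n - 16)/n); correct before setting the 3-sigma threshold
      n_inl <- sum(best_inliers)
      dof <- sqrt(n_inl / max(n_inl - 16L, 1L))
      # the threshold may grow as the consensus fit improves but never
      # shrinks below the initial scale estimate
      threshold <- max(3 * 1.4826 * median(r[best_inliers]) * dof,
                       threshold0, floor_thr)
    }
    new_inliers <- r <= threshold
    if (identical(new_inliers, best_inliers)) break
    best_inliers <- new_inliers
  }
  structure(list(coeffs = coeffs, inlier = best_inliers,
                 threshold = threshold, x_range = xr, y_range = yr),
            class = "focus_surface")
}

#' Predict focus height from a fitted surface
#'
#' @param object a `focus_surface` from [fit_focus_surface()].
#' @param x,y coordinates on the same scale as the fitted points.
#' @param ... unused.
#' @export
predict.focus_surface <- function(object, x, y, ...) {
  resc <- function(v, r) if (diff(r) > 0) 2 * (v - r[1]) / diff(r) - 1 else v * 0
  eval_focus_surface(object$coeffs, resc(x, object$x_range),
                     resc(y, object$y_range))
}

#' Autocorrelation (Vollath F4) focus score
#'
#' Sharpness measure `sum I(x,y) I(x+1,y) - sum I(x,y) I(x+2,y)` computed on
#' the mean-subtracted image, so a constant image scores exactly 0. The
#' score is maximal at best focus and decreases with defocus blur.
#'
#' @param image 2-D numeric matrix, at least 3 pixels along the first axis.
#' @return scalar focus score.
#' @export
autofocus_score <- function(image) {
  check_image(image)
  M <- nrow(image)
  if (M < 3L) stopf("image must be at least 3 px along the first axis")
  I <- image - mean(image)
  s1 <- sum(I[1:(M - 1), ] * I[2:M, ])
  s2 <- sum(I[1:(M - 2), ] * I[3:M, ])
  s1 - s2
}

#' Global focus offset from four feature drifts
#'
#' After each acquisition pass the focus drift is measured on four invariant
#' features; the global offset applied to all spots is the median of the
#' four drifts (the mean of the two middle values), which tolerates one
#' arbitrarily corrupted measurement.
#'
#' @param feature_drifts numeric vector of exactly four drift values (um).
#' @return scalar offset (um).
#' @export
global_focus_offset <- function(feature_drifts) {
  if (length(feature_drifts) != 4L)
    stopf("exactly four feature drifts are required")
  if (any(!is.finite(feature_drifts)))
    stopf("feature drifts must be finite")
  median(feature_drifts)
}
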