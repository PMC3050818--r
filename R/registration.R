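# Spot-grid registration: locate printed spots on a slide overview image and
# map them to microscope stage coordinates.

#' Apply the radial pincushion warp to point coordinates
#'
#' Forward distortion model `r' = r (1 + k r^2)`, with `r` the distance from
#' `center` divided by `r_scale`. This is the model assumed for the slide
#' overview camera; the coefficient is supplied by configuration, not
#' estimated here.
#'
#' @param xy n x 2 matrix of (x, y) coordinates (pixels).
#' @param k radial distortion coefficient (per squared normalized radius);
#'   positive = pincushion.
#' @param center distortion center (length 2).
#' @param r_scale radius normalization (pixels).
#' @return n x 2 matrix of warped coordinates.
#' @export
distort_points <- function(xy, k, center, r_scale) {
  xy <- rbind(xy)
  dx <- xy[, 1] - center[1]
  dy <- xy[, 2] - center[2]
  rn2 <- (dx^2 + dy^2) / r_scale^2
  f <- 1 + k * rn2
  cbind(center[1] + dx * f, center[2] + dy * f)
}

#' Invert the radial warp on point coordinates
#'
#' Solves `r (1 + k r^2) = r_obs` for each point by Newton iteration,
#' returning the undistorted coordinates. Errors if the warp is not
#' invertible (monotone) over the requested radii.
#'
#' @inheritParams distort_points
#' @export
undistort_points <- function(xy, k, center, r_scale) {
  xy <- rbind(xy)
  dx <- xy[, 1] - center[1]
  dy <- xy[, 2] - center[2]
  ro <- sqrt(dx^2 + dy^2) / r_scale
  r <- ro
  for (it in 1:50) {
    fp <- 1 + 3 * k * r^2
    if (any(fp <= 0)) stopf("radial warp with k = %g is not invertible here", k)
    step <- (r * (1 + k * r^2) - ro) / fp
    r <- r - step
    if (max(abs(step)) < 1e-14) break
  }
  scale <- ifelse(ro > 0, r / ro, 1)
  cbind(center[1] + dx * scale, center[2] + dy * scale)
}

#' Correct lens distortion in a slide overview image
#'
#' Removes pincushion distortion by resampling: each corrected pixel takes
#' its value from the observed image at the forward-warped position,
#' using bilinear interpolation. The distortion center is the image center.
#'
#' @param image 2-D numeric matrix.
#' @param k radial distortion coefficient (see [distort_points()]).
#' @return corrected image of the same size.
#' @export
correct_distortion <- function(image, k) {
  check_image(image)
  if (k == 0) return(image)
  H <- nrow(image); W <- ncol(image)
  center <- c((H + 1) / 2, (W + 1) / 2)
  r_scale <- min(H, W) / 2
  rn_max2 <- ((H - 1)^2 + (W - 1)^2) / 4 / r_scale^2
  if (1 + 3 * k * rn_max2 <= 0)
    stopf("warp with k = %g is not invertible within the image", k)
  xs <- rep(seq_len(H), W)
  ys <- rep(seq_len(W), each = H)
  src <- distort_points(cbind(xs, ys), k, center, r_scale)
  matrix(bilinear_sample(image, src[, 1], src[, 2], H, W), H, W)
}

# Bilinear interpolation of `image` at (sub-pixel) positions; returns a
# vector parallel to `x`; out-of-range positions return 0.
bilinear_sample <- function(image, x, y, H = nrow(image), W = ncol(image)) {
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 + 1 <= H & y0 + 1 <= W
  # clamp exact right/bottom edges into range
  edge_x <- x >= 1 & x <= H & x0 == H
  edge_y <- y >= 1 & y <= W & y0 == W
  x0[edge_x] <- H - 1L; fx[edge_x] <- 1
  y0[edge_y] <- W - 1L; fy[edge_y] <- 1
  ok <- ok | ((x0 >= 1 & x0 + 1 <= H) & (y0 >= 1 & y0 + 1 <= W) & (edge_x | edge_y))
  out <- numeric(length(x))
  if (any(ok)) {
    i00 <- (y0[ok] - 1) * H + x0[ok]
    v <- (1 - fx[ok]) * (1 - fy[ok]) * image[i00] +
      fx[ok] * (1 - fy[ok]) * image[i00 + 1] +
      (1 - fx[ok]) * fy[ok] * image[i00 + H] +
      fx[ok] * fy[ok] * image[i00 + H + 1]
    out[ok] <- v
  }
  out
}

#' Detect printed spots on a slide overview image
#'
#' The image is convolved with a unit-sum disk kernel of the spot diameter,
#' the convolved image is segmented by watershed (one basin per intensity
#' peak), and background basins are rejected by the same histogram rule used
#' for nuclear segmentation: a basin is kept only if its bright core exceeds
#' the first histogram peak by `intensity_offset` counts. The reported center
#' of each spot is the intensity-weighted centroid of the original
#' (background-subtracted) image over the basin core, giving sub-pixel
#' positions.
#'
#' @param slide_image 2-D numeric matrix, spots brighter than background.
#' @param spot_diameter_px printed spot diameter in pixels.
#' @param intensity_offset histogram-rule offset above the first image peak.
#' @param watershed_tolerance peak-merging tolerance of the watershed (counts).
#' @param min_area_px2 optional minimum core area; `NULL` disables.
#' @return data.frame of detected centers (`x_px`, `y_px`, `area_px2`,
#'   `total_intensity`), one row per spot.
#' @export
detect_spots <- function(slide_image, spot_diameter_px,
                         intensity_offset = 2000,
                         watershed_tolerance = 50,
                         min_area_px2 = NULL) {
  check_image(slide_image, "slide_image")
  d <- max(3L, as.integer(round(spot_diameter_px)))
  if (d %% 2L == 0L) d <- d + 1L
  kern <- EBImage::makeBrush(d, shape = "disc")
  kern <- kern / sum(kern)
  conv <- EBImage::filter2(slide_image, kern, boundary = "circular")
  conv <- matrix(as.numeric(conv), nrow(slide_image), ncol(slide_image))
  thr <- first_peak_threshold(conv, offset = intensity_offset)
  bg <- thr - intensity_offset
  segs <- basin_cores(conv, threshold = thr, background = bg,
                      tolerance = watershed_tolerance)
  if (length(segs$cores) == 0L)
    stopf("no spots detected (threshold %g, %d basins examined)",
          thr, segs$n_basins)
  H <- nrow(slide_image)
  res <- lapply(segs$cores, function(idx) {
    w <- pmax(slide_image[idx] - bg, 0)
    x <- ((idx - 1L) %% H) + 1L
    y <- ((idx - 1L) %/% H) + 1L
    sw <- sum(w)
    if (sw <= 0) {
      c(mean(x), mean(y), length(idx), 0)
    } else {
      c(sum(w * x) / sw, sum(w * y) / sw, length(idx), sum(slide_image[idx]))
    }
  })
  res <- do.call(rbind, res)
  out <- data.frame(x_px = res[, 1], y_px = res[, 2],
                    area_px2 = res[, 3], total_intensity = res[, 4])
  if (!is.null(min_area_px2)) out <- out[out$area_px2 >= min_area_px2, , drop = FALSE]
  if (nrow(out) == 0L) stopf("no spots detected after area filtering")
  rownames(out) <- NULL
  out
}

#' Map detected spot centers to stage coordinates
#'
#' The unique affine transform fixed by three anchor spots (pixel position
#' and measured stage position at the array corners) is applied to all
#' centers. Two invariant edge features of the slide, when given, are stored
#' as slide-relative offsets so the mapping can be re-used across
#' re-mountings.
#'
#' @param centers_px n x 2 matrix or data.frame of detected centers (px).
#' @param anchors data.frame with columns `x_px`, `y_px`, `x_um`, `y_um`;
#'   exactly three non-collinear rows.
#' @param edge_features optional data.frame, same columns, two rows.
#' @return list with `centers_um` (data.frame `x_um`, `y_um`), `affine`
#'   (list `A`, `b`), and `edge_offsets_um` (or `NULL`).
#' @export
map_to_stage <- function(centers_px, anchors, edge_features = NULL) {
  centers_px <- as.matrix(rbind(as.data.frame(centers_px)[, 1:2]))
  if (nrow(anchors) != 3L) stopf("exactly three anchors are required")
  P <- cbind(anchors$x_px, anchors$y_px, 1)
  if (abs(det(P)) < 1e-9 * max(abs(P))^2)
    stopf("anchor pixel positions are collinear")
  sol <- solve(P, cbind(anchors$x_um, anchors$y_um))
  A <- t(sol[1:2, ])
  b <- sol[3, ]
  mapped <- sweep(centers_px %*% t(A), 2, b, "+")
  edge <- NULL
  if (!is.null(edge_features)) {
    ep <- cbind(edge_features$x_px, edge_features$y_px)
    em <- sweep(ep %*% t(A), 2, b, "+")
    edge <- data.frame(x_um = edge_features$x_um, y_um = edge_features$y_um,
                       dx_um = edge_features$x_um - em[, 1],
                       dy_um = edge_features$y_um - em[, 2])
  }
  list(centers_um = data.frame(x_um = mapped[, 1], y_um = mapped[, 2]),
       affine = list(A = A, b = b),
       edge_offsets_um = edge)
}

#' Assign grid indices to mapped spot centers
#'
#' Each center is assigned the nearest expected grid node at the given
#' spacing, measured from the minimum mapped coordinates. Ties round toward
#' the smaller row, then the smaller column.
#'
#' @param centers_um data.frame with `x_um`, `y_um` (rows increase with x).
#' @param spacing_um grid spacing.
#' @param origin_um optional c(x, y) of grid node (1, 1); defaults to the
#'   minimum observed coordinates.
#' @return the input with integer `row` and `col` columns added.
#' @export
assign_grid_indices <- function(centers_um, spacing_um = 900, origin_um = NULL) {
  if (is.null(origin_um))
    origin_um <- c(min(centers_um$x_um), min(centers_um$y_um))
  # ceiling(v - 0.5) rounds halves downward -> smaller index wins ties
  centers_um$row <- as.integer(ceiling((centers_um$x_um - origin_um[1]) / spacing_um - 0.5)) + 1L
  centers_um$col <- as.integer(ceiling((centers_um$y_um - origin_um[2]) / spacing_um - 0.5)) + 1L
  centers_um
}
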