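# Synthetic living-microarray data with complete ground truth.
#
# The generator emulates the acquisition regime of the platform: dual-channel
# (Venus = inducible reporter, ECFP = constitutive control) time-lapse movies
# of reverse-transfected nuclei, slide overview images of the printed spot
# grid, and noisy samples of the slide's focus surface. Every output carries
# the ground truth needed to score segmentation, tracking, registration and
# surface fitting.

#' Calibrate the responder fold-change distribution
#'
#' Responding cells draw their induction fold from a lognormal; non-responders
#' have fold 1. Given the responder fraction of the mixture and two target tail
#' probabilities of the *overall* cell population -- the fraction induced less
#' than 3-fold and the fraction induced more than 50-fold -- the two lognormal
#' parameters are identified exactly from the corresponding normal quantiles.
#'
#' With the defaults (responder fraction 0.5, 55.7% below 3-fold, 8.3% above
#' 50-fold) the responder fold distribution has median `exp(fold_logmean)`
#' of about 14, consistent with strong but heterogeneous induction.
#'
#' @param responder_fraction fraction of cells that respond at all.
#' @param p_below_3 target overall fraction with fold < 3 (non-responders
#'   included; they always count here since their fold is 1).
#' @param p_above_50 target overall fraction with fold > 50.
#' @return list with `fold_logmean` and `fold_logsd`.
#' @export
calibrate_fold_params <- function(responder_fraction = 0.5,
                                  p_below_3 = 0.557,
                                  p_above_50 = 0.083) {
  if (responder_fraction <= 0 || responder_fraction > 1)
    stopf("responder_fraction must be in (0, 1]")
  p1 <- (p_below_3 - (1 - responder_fraction)) / responder_fraction
  p2 <- 1 - p_above_50 / responder_fraction
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1 || p2 <= p1)
    stopf("targets unattainable at responder_fraction = %g", responder_fraction)
  z1 <- qnorm(p1)
  z2 <- qnorm(p2)
  sdlog <- (log(50) - log(3)) / (z2 - z1)
  meanlog <- log(3) - z1 * sdlog
  list(fold_logmean = meanlog, fold_logsd = sdlog)
}

#' Simulation configuration
#'
#' Defaults describe one imaged field of the platform: a 512x512 EMCCD frame
#' (0.8 um pixels) holding ~85 nuclei, imaged every 20 minutes for 72 frames
#' (24 h). Plasmid copy number is lognormal and drives both channels; half the
#' cells respond, with heavy-tailed lognormal induction folds calibrated by
#' [calibrate_fold_params()]. Nuclei are textured ellipses performing a random
#' walk with small per-frame rotations; the camera adds a constant offset,
#' Gaussian read noise and optional shot noise, and illumination varies
#' smoothly across the field.
#'
#' @param field_size_px image height/width in pixels (length-2 integer).
#' @param n_frames number of time points.
#' @param frame_interval_min minutes between frames.
#' @param n_cells nuclei per field.
#' @param pixel_size_um microns per pixel.
#' @param copy_number_logmean,copy_number_logsd lognormal plasmid copy number
#'   (relative units; the median cell has copy number 1).
#' @param responder_fraction fraction of cells that induce at all.
#' @param fold_logmean,fold_logsd lognormal induction fold for responders;
#'   defaults are calibrated against the 55.7% / 8.3% fold-bin fractions.
#' @param induction_delay_range_min responders start induction at a uniform
#'   random delay in this range (minutes).
#' @param rise_time_min time for the logistic ramp to go from ~2% to ~98% of
#'   its span.
#' @param motion_sigma_px_per_frame random-walk step SD.
#' @param rotation_sigma_deg_per_frame per-frame nuclear rotation SD.
#' @param camera_offset constant camera bias (counts).
#' @param read_noise_sd Gaussian read noise SD (counts).
#' @param shot_noise logical; add Poisson-like noise with variance equal to
#'   the signal.
#' @param illumination_gradient_amplitude relative amplitude of a linear
#'   illumination gradient across the field (0 disables).
#' @param ecfp_per_copy,venus_baseline_per_copy mean within-nucleus pixel
#'   intensity (counts above offset) contributed per unit copy number; Venus
#'   scales further with the fold-change ramp.
#' @param texture_amplitude relative amplitude of the fixed per-cell nuclear
#'   speckle texture.
#' @param edge_softness_px optical softness of the nuclear edge: intensity
#'   rolls off smoothly over roughly this many pixels at the ellipse
#'   boundary, as diffraction blurs real nuclei.
#' @param min_center_distance_px minimum distance between nucleus centers at
#'   placement.
#' @param exclusion_radius_px nuclei cannot interpenetrate: a random-walk
#'   step bringing two centers closer than this is not taken (the cell
#'   pauses for that frame). Set 0 to disable.
#' @param n_occlusions number of transient occlusion events (a cell becomes
#'   invisible for 1-3 frames), used to exercise gap-closing in tracking.
#' @param rng_seed integer seed; identical configs give byte-identical output.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(field_size_px = c(512L, 512L),
                              n_frames = 72L,
                              frame_interval_min = 20,
                              n_cells = 85L,
                              pixel_size_um = 0.8,
                              copy_number_logmean = 0,
                              copy_number_logsd = 0.4,
                              responder_fraction = 0.5,
                              fold_logmean = NULL,
                              fold_logsd = NULL,
                              induction_delay_range_min = c(60, 300),
                              rise_time_min = 240,
                              motion_sigma_px_per_frame = 2,
                              rotation_sigma_deg_per_frame = 3,
                              camera_offset = 1000,
                              read_noise_sd = 30,
                              shot_noise = TRUE,
                              illumination_gradient_amplitude = 0.1,
                              ecfp_per_copy = 10000,
                              venus_baseline_per_copy = 150,
                              texture_amplitude = 0.25,
                              edge_softness_px = 0.7,
                              min_center_distance_px = 24,
                              exclusion_radius_px = 18,
                              n_occlusions = 0L,
                              rng_seed = 1L) {
  if (is.null(fold_logmean) || is.null(fold_logsd)) {
    # fixed study calibration: responder folds are calibrated once against
    # the reference mixture (responder fraction 0.5), independent of the
    # responder fraction actually simulated
    fp <- calibrate_fold_params(0.5)
    if (is.null(fold_logmean)) fold_logmean <- fp$fold_logmean
    if (is.null(fold_logsd)) fold_logsd <- fp$fold_logsd
  }
  cfg <- list(
    field_size_px = as.integer(rep_len(field_size_px, 2L)),
    n_frames = as.integer(n_frames),
    frame_interval_min = frame_interval_min,
    n_cells = as.integer(n_cells),
    pixel_size_um = pixel_size_um,
    copy_number_logmean = copy_number_logmean,
    copy_number_logsd = copy_number_logsd,
    responder_fraction = responder_fraction,
    fold_logmean = fold_logmean,
    fold_logsd = fold_logsd,
    induction_delay_range_min = rep_len(induction_delay_range_min, 2L),
    rise_time_min = rise_time_min,
    motion_sigma_px_per_frame = motion_sigma_px_per_frame,
    rotation_sigma_deg_per_frame = rotation_sigma_deg_per_frame,
    camera_offset = camera_offset,
    read_noise_sd = read_noise_sd,
    shot_noise = isTRUE(shot_noise),
    illumination_gradient_amplitude = illumination_gradient_amplitude,
    ecfp_per_copy = ecfp_per_copy,
    venus_baseline_per_copy = venus_baseline_per_copy,
    texture_amplitude = texture_amplitude,
    edge_softness_px = edge_softness_px,
    min_center_distance_px = min_center_distance_px,
    exclusion_radius_px = exclusion_radius_px,
    n_occlusions = as.integer(n_occlusions),
    rng_seed = as.integer(rng_seed)
  )
  if (cfg$n_frames < 1L) stopf("n_frames must be >= 1")
  if (cfg$n_cells < 0L) stopf("n_cells must be >= 0")
  if (cfg$responder_fraction < 0 || cfg$responder_fraction > 1)
    stopf("responder_fraction must be in [0, 1]")
  for (f in c("copy_number_logsd", "motion_sigma_px_per_frame",
              "rotation_sigma_deg_per_frame", "read_noise_sd", "fold_logsd"))
    if (cfg[[f]] < 0) stopf("%s must be >= 0", f)
  class(cfg) <- "simulation_config"
  cfg
}

#' Sample per-cell ground-truth parameters
#'
#' Draws the per-cell parameters of the mixture model: lognormal plasmid copy
#' number, responder flag, lognormal induction fold (1 for non-responders)
#' and a uniform induction delay.
#'
#' @param n number of cells.
#' @param config a [simulation_config()].
#' @param seed optional seed (defaults to the config seed).
#' @return data.frame with columns `cell`, `copy_number`, `responder`,
#'   `fold`, `delay_min`.
#' @export
sample_cell_parameters <- function(n, config = simulation_config(),
                                   seed = config$rng_seed) {
  with_seed(seed, {
    copy_number <- rlnorm(n, config$copy_number_logmean, config$copy_number_logsd)
    responder <- runif(n) < config$responder_fraction
    fold <- ifelse(responder,
                   rlnorm(n, config$fold_logmean, config$fold_logsd), 1)
    delay <- runif(n, config$induction_delay_range_min[1],
                   config$induction_delay_range_min[2])
    data.frame(cell = seq_len(n), copy_number = copy_number,
               responder = responder, fold = fold, delay_min = delay)
  })
}

#' Logistic induction ramp
#'
#' The generator's induction kinetics: fold expression is 1 before the
#' delay and rises logistically to `fold`, centered at `delay + rise/2`
#' with scale `rise/8`, so the ramp covers ~2-98% of its span across
#' `[delay, delay + rise]`.
#'
#' @param t_min time in minutes.
#' @param fold asymptotic fold change.
#' @param delay_min induction delay (minutes).
#' @param rise_min rise time (minutes).
#' @return fold expression at `t_min` (vectorized over all arguments).
#' @export
induction_ramp <- function(t_min, fold, delay_min, rise_min) {
  1 + (fold - 1) * plogis((t_min - (delay_min + rise_min / 2)) / (rise_min / 8))
}

# Fixed per-cell speckle texture: a sum of Gaussian bumps in the cell's own
# coordinate frame, standardized over the ellipse footprint. Evaluating it
# analytically at rotated coordinates makes texture persistence under
# rotation exact rather than an interpolation artifact.
make_texture <- function(a, b, n_blobs = 6L, amplitude = 0.25) {
  th <- runif(n_blobs, 0, 2 * pi)
  rr <- sqrt(runif(n_blobs))
  ub <- rr * cos(th) * a
  vb <- rr * sin(th) * b
  sb <- runif(n_blobs, 0.45, 0.8) * sqrt(a * b)
  ab <- rnorm(n_blobs)
  raw <- function(u, v) {
    s <- 0
    for (k in seq_len(n_blobs))
      s <- s + ab[k] * exp(-((u - ub[k])^2 + (v - vb[k])^2) / (2 * sb[k]^2))
    s
  }
  # standardize over the ellipse footprint
  gs <- seq(-1, 1, length.out = 25)
  gu <- rep(gs * a, each = 25); gv <- rep(gs * b, 25)
  keep <- (gu / a)^2 + (gv / b)^2 <= 1
  vals <- raw(gu[keep], gv[keep])
  m <- mean(vals); s <- max(pop_sd(vals), 1e-9)
  function(u, v) pmax(1 + amplitude * (raw(u, v) - m) / s, 0.2)
}

place_cells <- function(n, H, W, min_dist, margin) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  if (2 * margin >= H || 2 * margin >= W)
    stopf("field too small for the configured nucleus size")
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 5000L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stopf("cannot place %d cells of minimum spacing %g px in a %dx%d field",
            n, min_dist, H, W)
    x <- runif(1, margin, H - margin)
    y <- runif(1, margin, W - margin)
    if (placed == 0L ||
        min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >= min_dist^2) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
    }
  }
  cbind(x = xs, y = ys)
}

#' Simulate one imaged field with ground truth
#'
#' Renders the dual-channel time-lapse stack of one transfected cell cluster.
#' Per cell, the ECFP total is proportional to its plasmid copy number and
#' constant over time up to noise; the Venus total starts at a baseline
#' proportional to copy number and, for responders, ramps logistically to
#' `fold` times baseline after the cell's induction delay. Nuclei are
#' textured ellipses that translate by a random walk (reflected at the field
#' margin) and rotate by small per-frame angles; their speckle texture is
#' fixed in the cell frame, so it persists across frames up to rotation.
#'
#' @param config a [simulation_config()].
#' @return object of class `field_stack`: lists `venus` and `ecfp` of integer
#'   frame matrices, `timestamps` (minutes), pixel calibration, and a `truth`
#'   list with per-frame label `masks`, the per-cell parameter table `cells`,
#'   and per-frame `positions` (cell, frame, x, y, angle_deg, visible).
#' @export
simulate_field <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  H <- config$field_size_px[1]; W <- config$field_size_px[2]
  n <- config$n_cells
  nf <- config$n_frames
  t_min <- (seq_len(nf) - 1L) * config$frame_interval_min

  with_seed(config$rng_seed, {
    cells <- sample_cell_parameters(n, config, seed = NULL)

    # geometry: ellipse axes around equivalent radius ~7 px, ratio U(1, 1.5)
    r_eq <- runif(n, 6.7, 7.3)
    ratio <- runif(n, 1.0, 1.5)
    ax_a <- r_eq * sqrt(ratio)
    ax_b <- r_eq / sqrt(ratio)
    margin <- ceiling(max(ax_a, 0) + 6)
    pos0 <- place_cells(n, H, W, config$min_center_distance_px, margin)
    textures <- lapply(seq_len(n), function(i)
      make_texture(ax_a[i], ax_b[i], amplitude = config$texture_amplitude))

    # random-walk positions, reflected into [margin, H-margin]
    reflect <- function(v, lo, hi) {
      span <- hi - lo
      v <- (v - lo) %% (2 * span)
      lo + ifelse(v > span, 2 * span - v, v)
    }
    xs <- matrix(0, n, nf); ys <- matrix(0, n, nf); ang <- matrix(0, n, nf)
    if (n > 0) {
      xs[, 1] <- pos0[, "x"]; ys[, 1] <- pos0[, "y"]
      ang[, 1] <- runif(n, 0, 360)
      if (nf > 1) {
        for (t in 2:nf) {
          px <- reflect(xs[, t - 1] + rnorm(n, 0, config$motion_sigma_px_per_frame),
                        margin, H - margin)
          py <- reflect(ys[, t - 1] + rnorm(n, 0, config$motion_sigma_px_per_frame),
                        margin, W - margin)
          if (config$exclusion_radius_px > 0 && n > 1) {
            # nuclei exclude each other: reject steps that interpenetrate
            for (i in seq_len(n)) {
              d2 <- (px[-i] - px[i])^2 + (py[-i] - py[i])^2
              if (min(d2) < config$exclusion_radius_px^2) {
                px[i] <- xs[i, t - 1]
                py[i] <- ys[i, t - 1]
              }
            }
          }
          xs[, t] <- px
          ys[, t] <- py
          ang[, t] <- ang[, t - 1] + rnorm(n, 0, config$rotation_sigma_deg_per_frame)
        }
      }
    }

    # occlusion events: a cell transiently disappears for 1-3 frames
    visible <- matrix(TRUE, n, nf)
    if (config$n_occlusions > 0L && n > 0L && nf > 2L) {
      for (k in seq_len(config$n_occlusions)) {
        ci <- sample.int(n, 1L)
        dur <- sample.int(3L, 1L)
        start <- sample(seq(2L, max(2L, nf - dur)), 1L)
        visible[ci, start:min(nf, start + dur - 1L)] <- FALSE
      }
    }

    # illumination gradient: fixed random direction, linear across the field
    gdir <- runif(1, 0, 2 * pi)
    illum <- 1 + config$illumination_gradient_amplitude *
      (cos(gdir) * (row(matrix(0, H, W)) / H - 0.5) +
       sin(gdir) * (col(matrix(0, H, W)) / W - 0.5))

    venus <- vector("list", nf)
    ecfp <- vector("list", nf)
    masks <- vector("list", nf)
    pos_rows <- vector("list", nf)

    for (t in seq_len(nf)) {
      sig_v <- matrix(0, H, W)
      sig_c <- matrix(0, H, W)
      lab <- matrix(0L, H, W)
      best <- matrix(0, H, W)
      ramp <- if (n > 0)
        induction_ramp(t_min[t], cells$fold, cells$delay_min, config$rise_time_min)
      else numeric(0)
      for (i in seq_len(n)) {
        if (!visible[i, t]) next
        cxi <- xs[i, t]; cyi <- ys[i, t]
        rb <- ceiling(ax_a[i]) + 4L
        x0 <- max(1L, floor(cxi) - rb); x1 <- min(H, ceiling(cxi) + rb)
        y0 <- max(1L, floor(cyi) - rb); y1 <- min(W, ceiling(cyi) + rb)
        bx <- x0:x1; by <- y0:y1
        dx <- outer(bx - cxi, rep(1, length(by)))
        dy <- outer(rep(1, length(bx)), by - cyi)
        th <- ang[i, t] * pi / 180
        u <- cos(th) * dx + sin(th) * dy
        v <- -sin(th) * dx + cos(th) * dy
        rho <- sqrt((u / ax_a[i])^2 + (v / ax_b[i])^2)
        # smooth optical edge; the half-intensity contour is the ellipse
        edge <- plogis((1 - rho) * r_eq[i] / max(config$edge_softness_px, 1e-3))
        support <- rho <= 1.5
        inside <- rho <= 1
        if (!any(support)) next
        tex <- matrix(0, length(bx), length(by))
        tex[support] <- textures[[i]](u[support], v[support]) * edge[support]
        amp_c <- config$ecfp_per_copy * cells$copy_number[i]
        amp_v <- config$venus_baseline_per_copy * cells$copy_number[i] * ramp[i]
        sig_c[bx, by] <- sig_c[bx, by] + amp_c * tex
        sig_v[bx, by] <- sig_v[bx, by] + amp_v * tex
        contrib <- amp_c * tex
        sub_best <- best[bx, by]
        upd <- contrib > sub_best & inside
        if (any(upd)) {
          sub_lab <- lab[bx, by]
          sub_lab[upd] <- i
          sub_best[upd] <- contrib[upd]
          lab[bx, by] <- sub_lab
          best[bx, by] <- sub_best
        }
      }
      add_noise <- function(sig) {
        img <- config$camera_offset + sig * illum
        if (config$shot_noise)
          img <- img + rnorm(length(img), 0, 1) * sqrt(pmax(sig * illum, 0))
        if (config$read_noise_sd > 0)
          img <- img + rnorm(length(img), 0, config$read_noise_sd)
        matrix(as.integer(pmin(pmax(round(img), 0), 65535)), H, W)
      }
      venus[[t]] <- add_noise(sig_v)
      ecfp[[t]] <- add_noise(sig_c)
      masks[[t]] <- lab
      pos_rows[[t]] <- if (n > 0)
        data.frame(cell = seq_len(n), frame = t, x = xs[, t], y = ys[, t],
                   angle_deg = ang[, t], visible = visible[, t])
      else
        data.frame(cell = integer(0), frame = integer(0), x = numeric(0),
                   y = numeric(0), angle_deg = numeric(0), visible = logical(0))
    }

    structure(list(
      venus = venus,
      ecfp = ecfp,
      n_frames = nf,
      frame_interval_min = config$frame_interval_min,
      pixel_size_um = config$pixel_size_um,
      timestamps = t_min,
      truth = list(
        masks = masks,
        cells = cells,
        positions = do.call(rbind, pos_rows),
        geometry = data.frame(cell = seq_len(n), axis_a = ax_a, axis_b = ax_b),
        config = config
      )
    ), class = "field_stack")
  })
}

#' Simulate a printed spot-grid slide overview
#'
#' Renders an overview image of the printed transfection array: Gaussian
#' intensity spots on a regular grid, positions jittered and then warped by a
#' radial pincushion distortion `r' = r (1 + k r^2)` about the image center
#' (`r` normalized by half the smaller image dimension). The returned centers
#' are the true, undistorted spot positions.
#'
#' @param rows,cols grid dimensions (default 25 x 24 = 600 spots).
#' @param spacing_um center-to-center spot spacing.
#' @param spot_diameter_um printed spot diameter; the Gaussian profile sigma
#'   is a quarter of this.
#' @param distortion_coeff pincushion coefficient `k` (normalized radius).
#' @param jitter_sd_um SD of isotropic Gaussian printing jitter.
#' @param seed RNG seed.
#' @param pixel_size_um overview-image pixel size.
#' @param amplitude,offset,read_noise_sd intensity model of the overview
#'   camera (counts).
#' @param drop_fraction fraction of spots deleted at random (failed prints).
#' @return list with `image` (matrix, counts), `centers` (data.frame: row,
#'   col, x_px, y_px, x_um, y_um, present), and `pixel_size_um`.
#' @export
simulate_spot_grid <- function(rows = 25L, cols = 24L, spacing_um = 900,
                               spot_diameter_um = 400, distortion_coeff = 0,
                               jitter_sd_um = 0, seed = 1L,
                               pixel_size_um = 25, amplitude = 20000,
                               offset = 1000, read_noise_sd = 20,
                               drop_fraction = 0) {
  if (rows < 1L || cols < 1L) stopf("rows and cols must be >= 1")
  if (spacing_um < spot_diameter_um)
    stopf("spot spacing (%g um) smaller than spot diameter (%g um)",
          spacing_um, spot_diameter_um)
  with_seed(seed, {
    margin_um <- spacing_um
    H <- ceiling(((rows - 1) * spacing_um + 2 * margin_um) / pixel_size_um)
    W <- ceiling(((cols - 1) * spacing_um + 2 * margin_um) / pixel_size_um)
    grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
    x_um <- margin_um + (grid$row - 1) * spacing_um
    y_um <- margin_um + (grid$col - 1) * spacing_um
    nsp <- nrow(grid)
    if (jitter_sd_um > 0) {
      x_um <- x_um + rnorm(nsp, 0, jitter_sd_um)
      y_um <- y_um + rnorm(nsp, 0, jitter_sd_um)
    }
    present <- rep(TRUE, nsp)
    if (drop_fraction > 0)
      present[sample.int(nsp, round(drop_fraction * nsp))] <- FALSE
    x_px <- x_um / pixel_size_um + 0.5
    y_px <- y_um / pixel_size_um + 0.5
    center <- c((H + 1) / 2, (W + 1) / 2)
    warped <- distort_points(cbind(x_px, y_px), distortion_coeff,
                             center = center, r_scale = min(H, W) / 2)
    img <- matrix(0, H, W)
    sigma_px <- spot_diameter_um / 4 / pixel_size_um
    rb <- ceiling(4 * sigma_px)
    for (i in seq_len(nsp)) {
      if (!present[i]) next
      cx <- warped[i, 1]; cy <- warped[i, 2]
      x0 <- max(1L, floor(cx) - rb); x1 <- min(H, ceiling(cx) + rb)
      y0 <- max(1L, floor(cy) - rb); y1 <- min(W, ceiling(cy) + rb)
      if (x0 > x1 || y0 > y1) next
      bx <- x0:x1; by <- y0:y1
      d2 <- outer((bx - cx)^2, (by - cy)^2, "+")
      img[bx, by] <- img[bx, by] + amplitude * exp(-d2 / (2 * sigma_px^2))
    }
    img <- img + offset
    if (read_noise_sd > 0)
      img <- img + matrix(rnorm(H * W, 0, read_noise_sd), H, W)
    img <- matrix(pmin(pmax(round(img), 0), 65535), H, W)
    list(image = img,
         centers = data.frame(row = grid$row, col = grid$col,
                              x_px = x_px, y_px = y_px,
                              x_um = x_um, y_um = y_um, present = present),
         pixel_size_um = pixel_size_um)
  })
}

#' Simulate manual focus measurements on a cubic surface
#'
#' Samples the cubic focus surface `z(x, y)` at points evenly distributed
#' over the normalized slide area, adds Gaussian measurement noise, and
#' replaces a fixed fraction of the samples by gross outliers (as happens
#' when the manual focusing step locks onto debris).
#'
#' @param true_coeffs 4x4 coefficient matrix `a[i+1, j+1]` of
#'   `z = sum a_ij x^i y^j`, `x`,`y` in `[-1, 1]`.
#' @param n_points number of samples (default 45, the manual calibration set).
#' @param noise_sd Gaussian noise SD (um).
#' @param outlier_fraction fraction (< 0.5) of points replaced by outliers;
#'   the outlier count is `round(n_points * outlier_fraction)`.
#' @param outlier_sd magnitude scale of the gross outliers (um).
#' @param seed RNG seed.
#' @return data.frame with `x`, `y`, `z` and logical `outlier`.
#' @export
simulate_focus_samples <- function(true_coeffs, n_points = 45L, noise_sd = 0,
                                   outlier_fraction = 0, outlier_sd = 50,
                                   seed = 1L) {
  true_coeffs <- as.matrix(true_coeffs)
  if (!all(dim(true_coeffs) == c(4L, 4L)))
    stopf("true_coeffs must be a 4x4 matrix")
  if (outlier_fraction < 0 || outlier_fraction >= 0.5)
    stopf("outlier_fraction must be in [0, 0.5)")
  # near-square grid covering [-1,1]^2, truncated to n_points
  nr <- max(1L, floor(sqrt(n_points)))
  while (nr > 1L && n_points %% nr != 0L) nr <- nr - 1L
  nc <- ceiling(n_points / nr)
  gx <- if (nr == 1L) 0 else seq(-1, 1, length.out = nr)
  gy <- if (nc == 1L) 0 else seq(-1, 1, length.out = nc)
  pts <- expand.grid(x = gx, y = gy)[seq_len(n_points), ]
  with_seed(seed, {
    z <- eval_focus_surface(true_coeffs, pts$x, pts$y)
    if (noise_sd > 0) z <- z + rnorm(n_points, 0, noise_sd)
    out <- rep(FALSE, n_points)
    k <- round(n_points * outlier_fraction)
    if (k > 0) {
      idx <- sample.int(n_points, k)
      out[idx] <- TRUE
      z[idx] <- z[idx] + outlier_sd * sample(c(-1, 1), k, replace = TRUE) *
        runif(k, 0.8, 1.5)
    }
    data.frame(x = pts$x, y = pts$y, z = z, outlier = out)
  })
}
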