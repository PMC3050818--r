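# Synthetic-data generator: determinism, the cell mixture, geometry and
# texture, spot grids and focus samples.

test_that("identical configs give byte-identical fields", {
  cfg <- small_field_config(n_frames = 2L, n_cells = 5L, seed = 3L)
  a <- simulate_field(cfg)
  b <- simulate_field(cfg)
  expect_identical(a$venus, b$venus)
  expect_identical(a$ecfp, b$ecfp)
  expect_identical(a$truth$masks, b$truth$masks)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("a field with no cells is camera offset plus noise only", {
  cfg <- small_field_config(n_frames = 2L, n_cells = 0L, seed = 5L)
  fs <- simulate_field(cfg)
  expect_equal(nrow(fs$truth$cells), 0L)
  expect_true(all(fs$truth$masks[[1]] == 0L))
  m <- mean(fs$ecfp[[1]])
  expect_lt(abs(m - cfg$camera_offset), 2)       # mean within noise
  expect_lt(sd(as.numeric(fs$ecfp[[1]])), 2 * cfg$read_noise_sd)
})

test_that("responder_fraction 0 forces every true fold to 1", {
  cfg <- small_field_config(n_frames = 1L, n_cells = 20L, seed = 9L,
                            responder_fraction = 0,
                            fold_logmean = 1, fold_logsd = 1)
  fs <- simulate_field(cfg)
  expect_true(all(fs$truth$cells$fold == 1))
  expect_true(all(!fs$truth$cells$responder))
})

test_that("cells that cannot fit raise an error", {
  cfg <- small_field_config(n_frames = 1L, n_cells = 200L, seed = 1L)
  expect_error(simulate_field(cfg), "cannot place")
})

test_that("fold calibration reproduces the two tail fractions", {
  fp <- calibrate_fold_params(responder_fraction = 0.5)
  cfg <- simulation_config(responder_fraction = 0.5, rng_seed = 21L)
  pars <- sample_cell_parameters(10000L, cfg)
  expect_lt(abs(mean(pars$fold < 3) - 0.557), 0.015)
  expect_lt(abs(mean(pars$fold > 50) - 0.083), 0.010)
  # the closed-form quantile identities hold exactly
  p_resp_below3 <- (0.557 - 0.5) / 0.5
  expect_equal(plnorm(3, fp$fold_logmean, fp$fold_logsd), p_resp_below3,
               tolerance = 1e-12)
  expect_equal(1 - plnorm(50, fp$fold_logmean, fp$fold_logsd), 0.083 / 0.5,
               tolerance = 1e-12)
})

test_that("empirical responder fraction converges to the configured one", {
  cfg <- simulation_config(responder_fraction = 0.4, rng_seed = 33L)
  pars <- sample_cell_parameters(10000L, cfg)
  p_hat <- mean(pars$responder)
  ci <- 1.96 * sqrt(0.4 * 0.6 / 10000)
  expect_lt(abs(p_hat - 0.4), ci + 1e-9)
  expect_true(all(pars$fold[!pars$responder] == 1))
})

test_that("per-cell true ECFP totals are conserved over time up to noise", {
  fx <- small_field_fixture()
  fs <- fx$field
  offset <- fs$truth$config$camera_offset
  for (cid in seq_len(nrow(fs$truth$cells))) {
    tot <- vapply(seq_len(fs$n_frames), function(t) {
      idx <- fs$truth$masks[[t]] == cid
      sum(fs$ecfp[[t]][idx]) - offset * sum(idx)
    }, numeric(1))
    expect_lt(sd(tot) / mean(tot), 0.02)
  }
})

test_that("nuclear texture persists across frames up to rotation", {
  cfg <- small_field_config(n_frames = 2L, n_cells = 6L, seed = 77L,
                            read_noise_sd = 0, shot_noise = FALSE,
                            illumination_gradient_amplitude = 0,
                            motion_sigma_px_per_frame = 0,
                            rotation_sigma_deg_per_frame = 20)
  fs <- simulate_field(cfg)
  s1 <- segment_frame(fs$ecfp[[1]], small_seg_params())
  s2 <- segment_frame(fs$ecfp[[2]], small_seg_params())
  tp1 <- fs$truth$positions[fs$truth$positions$frame == 1, ]
  tp2 <- fs$truth$positions[fs$truth$positions$frame == 2, ]
  expect_equal(nrow(s1$cells), 6L)
  for (i in seq_len(nrow(s1$cells))) {
    ci <- which.min((tp1$x - s1$cells$x[i])^2 + (tp1$y - s1$cells$y[i])^2)
    j <- which.min((s2$cells$x - tp2$x[ci])^2 + (s2$cells$y - tp2$y[ci])^2)
    delta <- tp2$angle_deg[ci] - tp1$angle_deg[ci]
    rot <- rotate_patch(s1$patches[[i]], delta)
    u <- rot$mask & s2$patches[[j]]$mask
    expect_gt(cor(rot$values[u], s2$patches[[j]]$values[u]), 0.95)
  }
})

test_that("label masks assign every labelled pixel to exactly one cell", {
  fx <- small_field_fixture()
  m <- fx$field$truth$masks[[1]]
  expect_true(all(m >= 0 & m <= nrow(fx$field$truth$cells)))
  # areas are near the nominal nuclear footprint
  areas <- table(m[m > 0])
  expect_true(all(areas > 100 & areas < 260))
})

test_that("spot grids have the right count and exact maxima when clean", {
  sg <- simulate_spot_grid(rows = 5, cols = 4, seed = 2, jitter_sd_um = 0,
                           distortion_coeff = 0, read_noise_sd = 0)
  expect_equal(nrow(sg$centers), 20L)
  # rendered maxima at the true grid positions (to pixel resolution)
  for (i in seq_len(nrow(sg$centers))) {
    cx <- sg$centers$x_px[i]; cy <- sg$centers$y_px[i]
    win <- sg$image[round(cx) + (-8:8), round(cy) + (-8:8)]
    pk <- which(win == max(win), arr.ind = TRUE)[1, ]
    expect_lt(abs(pk[1] - 9 + round(cx) - cx), 1)
    expect_lt(abs(pk[2] - 9 + round(cy) - cy), 1)
  }
})

test_that("the standard array layout yields 600 spots", {
  sg <- simulate_spot_grid(rows = 25, cols = 24, spacing_um = 900, seed = 1)
  expect_equal(nrow(sg$centers), 600L)
})

test_that("spacing below the spot diameter errors", {
  expect_error(simulate_spot_grid(rows = 2, cols = 2, spacing_um = 300,
                                  spot_diameter_um = 400), "smaller")
})

test_that("pincushion warp displaces corner spots outward per the model", {
  k <- 0.06
  sg0 <- simulate_spot_grid(rows = 5, cols = 5, seed = 6, jitter_sd_um = 0,
                            distortion_coeff = 0, read_noise_sd = 0)
  H <- nrow(sg0$image); W <- ncol(sg0$image)
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  warped <- distort_points(cbind(sg0$centers$x_px, sg0$centers$y_px),
                           k, ctr, min(H, W) / 2)
  # analytic displacement: dr = r * k * rn^2, outward
  for (i in seq_len(nrow(sg0$centers))) {
    p0 <- c(sg0$centers$x_px[i], sg0$centers$y_px[i])
    rn2 <- sum((p0 - ctr)^2) / (min(H, W) / 2)^2
    expected <- ctr + (p0 - ctr) * (1 + k * rn2)
    expect_equal(as.numeric(warped[i, ]), expected, tolerance = 1e-12)
  }
})

test_that("focus samples are exact on the surface when noiseless", {
  cf <- matrix(c(3, 0.5, 0, 0.1,
                 0.2, -1, 0, 0,
                 0, 0, 0.3, 0,
                 -0.2, 0, 0, 0.05), 4, 4, byrow = TRUE)
  s <- simulate_focus_samples(cf, n_points = 45, noise_sd = 0,
                              outlier_fraction = 0, seed = 1)
  expect_equal(nrow(s), 45L)
  expect_equal(s$z, eval_focus_surface(cf, s$x, s$y), tolerance = 1e-12)
  expect_true(all(!s$outlier))
})

test_that("outlier count follows round(n * fraction)", {
  cf <- diag(4)
  s <- simulate_focus_samples(cf, n_points = 45, noise_sd = 0.1,
                              outlier_fraction = 0.1, outlier_sd = 50, seed = 3)
  expect_equal(sum(s$outlier), round(45 * 0.1))
  s2 <- simulate_focus_samples(cf, n_points = 40, noise_sd = 0,
                               outlier_fraction = 0.1, seed = 3)
  expect_equal(sum(s2$outlier), 4L)
})
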