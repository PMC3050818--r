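# Appearance scoring, strict and flexible linking, whole-field tracking.

test_that("identical patches score 0 at angle 0", {
  p <- analytic_patch(0)
  sc <- appearance_score(p, p)
  expect_equal(sc$score, 0)
  expect_equal(sc$angle, 0)
})

test_that("a patch against its on-grid rotation scores < 1e-6", {
  # linear ramps: bilinear resampling is exact, so only true interpolation
  # residual could remain
  p0 <- ramp_patch(0)
  for (ang in c(20, 90, 250)) {
    pr <- ramp_patch(ang)
    sc <- appearance_score(p0, pr, rotation_step_deg = 10)
    expect_lt(sc$score, 1e-6)
  }
  # a smooth curved pattern keeps the residual small but nonzero
  sc2 <- appearance_score(analytic_patch(0), analytic_patch(20))
  expect_lt(sc2$score, 1e-4)
})

test_that("all-zero versus all-one patches score 1", {
  a <- matrix(0, 32, 32)
  b <- matrix(1, 32, 32)
  expect_equal(appearance_score(a, b)$score, 1)
})

test_that("patch size mismatch errors", {
  expect_error(appearance_score(matrix(0, 16, 16), matrix(0, 32, 32)),
               "size")
})

make_cell <- function(x, y, angle = 0) {
  list(cells = data.frame(x = x, y = y), patch = analytic_patch(angle))
}

test_that("strict linking obeys the distance rule", {
  p <- analytic_patch(0)
  c1 <- data.frame(x = 50, y = 50)
  c2_near <- data.frame(x = 53, y = 54)   # 5 px
  c2_far <- data.frame(x = 50 + 12, y = 50)  # 12 px
  ln <- strict_link(c1, c2_near, list(p), list(p))
  expect_equal(nrow(ln), 1L)
  expect_equal(ln$from, 1L)
  ln2 <- strict_link(c1, c2_far, list(p), list(p))
  expect_equal(nrow(ln2), 0L)
})

test_that("discrepant candidate scores suppress the link", {
  # two nearly identical candidates within range -> ambiguous -> no link
  p <- analytic_patch(0)
  c1 <- data.frame(x = 50, y = 50)
  c2 <- data.frame(x = c(53, 47), y = c(50, 50))
  ln <- strict_link(c1, c2, list(p), list(p, p))
  expect_equal(nrow(ln), 0L)
  # one clearly better candidate -> linked to it
  pr <- analytic_patch(45)  # off-grid rotation, worse but under threshold?
  sc <- appearance_score(p, pr)$score
  if (sc > 0.0155 * 1.2) {
    ln2 <- strict_link(c1, c2, list(p), list(p, pr))
    expect_equal(nrow(ln2), 1L)
    expect_equal(ln2$to, 1L)
  }
})

test_that("lowering the appearance threshold never adds links", {
  fx <- small_field_fixture()
  recs <- fx$seg$records
  it <- which(recs$frame == 1); it1 <- which(recs$frame == 2)
  n_links <- vapply(c(0.0155, 0.008, 0.003, 0.001), function(thr) {
    nrow(strict_link(recs[it, ], recs[it1, ], fx$seg$patches[it],
                     fx$seg$patches[it1],
                     tracking_params(appearance_threshold = thr)))
  }, numeric(1))
  expect_true(all(diff(n_links) <= 0))
})

test_that("strict linking matches the brute-force assignment oracle", {
  cfgs <- list(
    small_field_config(n_frames = 2L, n_cells = 5L, seed = 41L),
    small_field_config(n_frames = 2L, n_cells = 6L, seed = 43L),
    small_field_config(n_frames = 2L, n_cells = 4L, seed = 47L)
  )
  for (cfg in cfgs) {
    fs <- simulate_field(cfg)
    sf <- segment_field(fs, small_seg_params())
    it <- which(sf$records$frame == 1); it1 <- which(sf$records$frame == 2)
    ln <- strict_link(sf$records[it, ], sf$records[it1, ],
                      sf$patches[it], sf$patches[it1])
    oracle <- brute_force_links(sf$records[it, ], sf$records[it1, ],
                                sf$patches[it], sf$patches[it1])
    ln <- ln[order(ln$from), ]
    expect_equal(ln$from, oracle$from)
    expect_equal(ln$to, oracle$to)
  }
})

test_that("strict linking recovers nearly all truth with no false links", {
  fx <- small_field_fixture()
  st <- strict_link_truth_stats(fx$seg$records, fx$seg$patches,
                                fx$field$truth)
  expect_equal(st$n_false, 0L)
  expect_gte(st$n_recovered / st$n_true, 0.95)
})

test_that("flexible linking bridges a dropped frame with a gap annotation", {
  # one cell, frames 1..6, frame 3 missing
  recs <- data.frame(frame = c(1, 2, 4, 5, 6), label = 1L,
                     x = c(10, 11, 13, 14, 15), y = 10,
                     area_px2 = 150, venus = 100, ecfp = 1000)
  p <- analytic_patch(0)
  patches <- rep(list(p), 5)
  tr <- track_field(recs, patches)
  expect_equal(max(tr$track_id), 1L)
  expect_equal(sum(tr$gap_before), 1L)
  expect_equal(tr$link_type[tr$frame == 4], "flexible")
})

test_that("a join far outside the intensity-difference pool is rejected", {
  # many same-gap candidates; one with a wildly different ECFP
  n <- 20
  recs_end <- data.frame(frame = 1, label = 1:n,
                         x = seq(10, 600, length.out = n),
                         y = 10, area_px2 = 150, venus = 0,
                         ecfp = 1000 + seq(0, 38, 2))
  recs_start <- data.frame(frame = 3, label = 1:n, x = recs_end$x + 2,
                           y = 10, area_px2 = 150, venus = 0,
                           ecfp = recs_end$ecfp + 1)
  recs_start$ecfp[n] <- recs_end$ecfp[n] + 5e4   # gross mismatch
  recs <- rbind(recs_end, recs_start)
  frags <- as.list(seq_len(2 * n))
  fl <- flexible_link(frags, recs, tracking_params())
  joined_ends <- fl$joins$from_rec
  expect_true(all(seq_len(n - 1) %in% joined_ends))
  expect_false(n %in% joined_ends)
})

test_that("occluded cells are re-joined to the correct fragments", {
  cfg <- small_field_config(n_frames = 30L, n_cells = 20L, seed = 55L,
                            n_occlusions = 6L)
  fs <- simulate_field(cfg)
  sf <- segment_field(fs, small_seg_params())
  tr <- track_field(sf$records, sf$patches)
  expect_equal(max(tr$track_id), 20L)
  fl <- track_error_flags(tr, fs$truth)
  expect_equal(sum(fl), 0L)
  expect_gt(sum(tr$gap_before > 0), 0L)   # at least one annotated gap
})

test_that("a single static cell yields one full-length track", {
  cfg <- small_field_config(n_frames = 10L, n_cells = 1L, seed = 61L,
                            motion_sigma_px_per_frame = 0)
  fs <- simulate_field(cfg)
  sf <- segment_field(fs, small_seg_params())
  tr <- track_field(sf$records, sf$patches)
  expect_equal(max(tr$track_id), 1L)
  expect_equal(nrow(tr), 10L)
  expect_true(all(diff(tr$frame) == 1))
})

test_that("tracks form a partition: every record in exactly one track", {
  fx <- small_field_fixture()
  tr <- track_field(fx$seg$records, fx$seg$patches)
  expect_equal(nrow(tr), nrow(fx$seg$records))
  # no track holds two records from one frame
  key <- paste(tr$track_id, tr$frame)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("fields processed in either order give identical tracks", {
  fx <- small_field_fixture()
  cfg2 <- small_field_config(seed = 8L)
  fs2 <- simulate_field(cfg2)
  sf2 <- segment_field(fs2, small_seg_params())
  t_a1 <- track_field(fx$seg$records, fx$seg$patches)
  t_b1 <- track_field(sf2$records, sf2$patches)
  t_b2 <- track_field(sf2$records, sf2$patches)
  t_a2 <- track_field(fx$seg$records, fx$seg$patches)
  expect_identical(t_a1, t_a2)
  expect_identical(t_b1, t_b2)
})

test_that("pixel calibration is consistent between the distance and area rules", {
  cfg <- simulation_config()
  expect_equal(cfg$pixel_size_um, 0.8)
  expect_equal(tracking_params()$max_distance_px * cfg$pixel_size_um, 8)
  expect_equal(125 * cfg$pixel_size_um^2, 80)
})
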