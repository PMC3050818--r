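# Induction statistics: normalization, responder calling, fold bins, CVs,
# spot curves, replicate subsampling and QC arithmetic.

toy_tracks <- function() {
  # 3 tracks x 6 frames; track 3 induces 5-fold after frame 3
  fr <- 1:6
  rbind(
    data.frame(track_id = 1L, frame = fr, venus = 100, ecfp = 1000),
    data.frame(track_id = 2L, frame = fr, venus = 300, ecfp = 3000),
    data.frame(track_id = 3L, frame = fr,
               venus = c(100, 100, 100, 300, 500, 500), ecfp = 1000)
  )
}

test_that("normalized profiles are invariant to shared channel scaling", {
  tr <- toy_tracks()
  n0 <- normalize_profiles(tr)
  tr2 <- tr
  tr2$venus <- tr2$venus * 7
  tr2$ecfp <- tr2$ecfp * 7
  n1 <- normalize_profiles(tr2)
  expect_equal(n1$profiles$r, n0$profiles$r)
  expect_equal(n1$cells$peak_fold, n0$cells$peak_fold)
})

test_that("constant channels give fold 1 everywhere", {
  n <- normalize_profiles(toy_tracks())
  expect_true(all(abs(n$profiles$fold[n$profiles$track_id %in% 1:2] - 1) < 1e-12))
  expect_equal(n$cells$peak_fold[n$cells$track_id == 3], 5)
})

test_that("tracks shorter than the baseline window are excluded with a log", {
  tr <- rbind(toy_tracks(),
              data.frame(track_id = 4L, frame = 1:2, venus = 1, ecfp = 1))
  n <- normalize_profiles(tr, baseline_frames = 3)
  expect_false(4L %in% n$cells$track_id)
  expect_true(4L %in% n$excluded$track_id)
})

test_that("zero-ECFP frames are excluded and flagged", {
  tr <- toy_tracks()
  tr$ecfp[tr$track_id == 1 & tr$frame == 5] <- 0
  n <- normalize_profiles(tr)
  expect_false(any(n$profiles$track_id == 1 & n$profiles$frame == 5))
})

test_that("responder classification implements the 3-SD rule", {
  # degenerate SD: identical initial values; any later rise is a response
  v <- rbind(data.frame(track_id = 1:4, frame = 1, value = 1),
             data.frame(track_id = 1:4, frame = 2,
                        value = c(1, 1, 1.01, 1)))
  cl <- classify_responders(v, signal = "value")
  expect_equal(cl$threshold, 1)
  expect_equal(cl$flags$responder, c(FALSE, FALSE, TRUE, FALSE))

  # flat population: no responders
  v2 <- rbind(data.frame(track_id = 1:5, frame = 1, value = c(1, 2, 3, 4, 5)),
              data.frame(track_id = 1:5, frame = 2, value = c(1, 2, 3, 4, 5)))
  cl2 <- classify_responders(v2, signal = "value")
  expect_true(all(!cl2$flags$responder))

  expect_error(classify_responders(
    data.frame(track_id = 1, frame = 1, value = 1), signal = "value"),
    "2 cells")
})

test_that("responder calling is monotone in later-frame signal", {
  set.seed(10)
  v <- rbind(data.frame(track_id = 1:10, frame = 1, value = rnorm(10, 1, 0.1)),
             data.frame(track_id = 1:10, frame = 2, value = rnorm(10, 1, 0.1)))
  cl <- classify_responders(v, signal = "value")
  v_up <- v
  bump <- v_up$frame == 2 & v_up$track_id == 4
  v_up$value[bump] <- v_up$value[bump] + 10
  cl_up <- classify_responders(v_up, signal = "value")
  was <- cl$flags$responder
  now <- cl_up$flags$responder
  expect_true(all(now[was]))       # no responder is un-called
  expect_true(now[cl_up$flags$track_id == 4])
})

test_that("fold bins reproduce the printed fractions", {
  folds <- c(rep(1, 3532), rep(10, 6339 - 3532 - 523), rep(60, 523))
  fd <- fold_distribution(folds)
  expect_equal(fd$count, c(3532, 2284, 523))
  expect_equal(fd$fraction_pct[1], 55.7)
  expect_equal(fd$fraction_pct[3], 8.3)
  expect_lt(abs(sum(fd$fraction_pct) - 100), 0.11)

  fd2 <- fold_distribution(rep(1, 50))
  expect_equal(fd2$fraction_pct, c(100, 0, 0))
  expect_error(fold_distribution(numeric(0)), "no fold")
})

test_that("responder CV uses the population-SD convention", {
  expect_equal(responder_cv(c(5, 5, 5)), 0)
  expect_equal(responder_cv(c(9, 10, 11)), 100 * sqrt(2 / 3) / 10,
               tolerance = 1e-12)
  expect_equal(round(responder_cv(c(9, 10, 11)), 3), 8.165)
  expect_error(responder_cv(7), "2 responders")
})

test_that("spot curves average cells per spot and spots per frame", {
  tr <- toy_tracks()
  sm <- data.frame(track_id = 1:3, spot_id = c(1L, 1L, 2L))
  sc <- spot_curves(tr, sm)
  s1 <- sc$spots[sc$spots$spot_id == 1 & sc$spots$frame == 1, ]
  expect_equal(s1$mean_venus, 200)
  expect_equal(s1$mean_ecfp, 2000)
  expect_equal(s1$n_cells, 2L)
  # single-cell spot equals that cell's series
  s2 <- sc$spots[sc$spots$spot_id == 2, ]
  expect_equal(s2$mean_venus, tr$venus[tr$track_id == 3])
  # two identical spots: across-spot mean equals either spot
  tr2 <- rbind(toy_tracks(),
               transform(toy_tracks(), track_id = track_id + 10L))
  sm2 <- data.frame(track_id = c(1:3, 11:13), spot_id = rep(1:2, each = 3))
  sc2 <- spot_curves(tr2, sm2)
  sp <- sc2$spots[sc2$spots$spot_id == 1, ]
  expect_equal(sc2$mean_curve$mean_venus, sp$mean_venus)
  expect_error(spot_curves(tr, sm[1:2, ]), "without spot")
})

test_that("replicate subsampling is reproducible and statistically sane", {
  set.seed(30)
  vals <- rnorm(75)
  a <- replicate_subsampling(vals, seed = 9)
  b <- replicate_subsampling(vals, seed = 9)
  expect_identical(a, b)
  # SD of subset means decreases monotonically in n (tolerating MC noise)
  sdm <- a$stats$sd_of_means
  expect_true(all(diff(sdm) < 0.02))
  # n = population size recovers the population SD exactly
  full <- replicate_subsampling(vals, n_range = 75L, n_perm = 3L, seed = 1)
  expect_equal(full$stats$mean_sd, full$population_sd, tolerance = 1e-12)
  expect_true(full$stats$adequate)
  # constant values: every n adequate
  const <- replicate_subsampling(rep(4, 30), n_range = 1:5, n_perm = 10L,
                                 seed = 1)
  expect_true(all(const$stats$adequate))
  expect_error(replicate_subsampling(rnorm(10), n_range = 1:20), "exceeds")
})

test_that("subset-mean SDs follow sampling theory", {
  set.seed(31)
  vals <- rnorm(75)
  rs <- replicate_subsampling(vals, n_range = 3:20, n_perm = 1000L, seed = 17)
  sd_pop <- rs$population_sd
  n <- rs$stats$n
  # exact SRSWOR theory: sd(mean) = sd_pop/sqrt(n) * fpc
  theory <- sd_pop / sqrt(n) * sqrt((75 - n) / 74)
  expect_true(all(abs(rs$stats$sd_of_means / theory - 1) < 0.15))
})

test_that("QC error-rate arithmetic matches hand computation", {
  expect_equal(error_rate(c(rep(TRUE, 14), rep(FALSE, 2340 - 14))), 0.6)
  expect_equal(error_rate(rep(FALSE, 100)), 0)
  expect_equal(error_rate(c(TRUE, rep(FALSE, 7))), 12.5)
  expect_error(error_rate(logical(0)), "no cells")
})
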