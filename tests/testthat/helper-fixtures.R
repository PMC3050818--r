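# Shared fixtures and oracles. Heavy fixtures are built lazily and cached
# for the session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A quick field: 256 px, 12 cells, few frames. The low-pass diameter is
# scaled with image size (69 * 256/512 ~ 35) to stay in the filter's design
# regime.
small_field_config <- function(n_frames = 4L, n_cells = 12L, seed = 7L, ...) {
  simulation_config(field_size_px = c(256L, 256L), n_frames = n_frames,
                    n_cells = n_cells, rng_seed = seed, ...)
}

small_seg_params <- function(...) segmentation_params(lowpass_diameter_px = 35, ...)

small_field_fixture <- function() {
  cached("small_field", {
    fs <- simulate_field(small_field_config())
    sf <- segment_field(fs, small_seg_params())
    list(field = fs, seg = sf)
  })
}

# The replicate-slide fixture: three full default fields (512 px, 85 cells,
# 72 frames), segmented and tracked, with per-field ground truth retained.
# This is the study-scale fixture shared by the acceptance suite; three
# replicate fields (~255 cells) give the binomial resolution the recovery
# checks need while keeping the suite inside a practical runtime.
replicate_slide_fixture <- function() {
  cached("replicate_slide", {
    fields <- lapply(1:3, function(f) {
      sim <- simulation_config(rng_seed = 42L + 1000L * f)
      fs <- simulate_field(sim)
      sf <- segment_field(fs)
      tr <- track_field(sf$records, sf$patches)
      list(field = fs, seg = sf, tracks = tr)
    })
    fields
  })
}

pooled_slide_tracks <- function(fixture) {
  out <- list()
  offset <- 0L
  for (f in seq_along(fixture)) {
    tr <- fixture[[f]]$tracks
    tr$track_id <- tr$track_id + offset
    tr$field <- f
    offset <- max(tr$track_id)
    out[[f]] <- tr
  }
  do.call(rbind, out)
}

# Match each record to the nearest visible true cell (NA if > 6 px away).
match_records_to_truth <- function(records, truth, max_dist = 6) {
  vapply(seq_len(nrow(records)), function(i) {
    tp <- truth$positions[truth$positions$frame == records$frame[i] &
                            truth$positions$visible, , drop = FALSE]
    if (nrow(tp) == 0L) return(NA_integer_)
    d2 <- (tp$x - records$x[i])^2 + (tp$y - records$y[i])^2
    j <- which.min(d2)
    if (d2[j] <= max_dist^2) tp$cell[j] else NA_integer_
  }, integer(1))
}

# Strict-link scoring against ground truth over all consecutive transitions.
# Recovery is conditional on both endpoints having been segmented.
strict_link_truth_stats <- function(records, patches, truth,
                                    params = tracking_params()) {
  tcell <- match_records_to_truth(records, truth)
  frames <- sort(unique(records$frame))
  tot <- 0L; rec <- 0L; fp <- 0L
  for (k in seq_len(length(frames) - 1L)) {
    if (frames[k + 1] - frames[k] != 1) next
    it <- which(records$frame == frames[k])
    it1 <- which(records$frame == frames[k + 1])
    ln <- strict_link(records[it, ], records[it1, ],
                      patches[it], patches[it1], params)
    shared <- intersect(tcell[it], tcell[it1])
    tot <- tot + sum(!is.na(shared))
    if (nrow(ln) > 0L) {
      ok <- tcell[it[ln$from]] == tcell[it1[ln$to]]
      rec <- rec + sum(ok, na.rm = TRUE)
      fp <- fp + sum(!ok | is.na(ok))
    }
  }
  list(n_true = tot, n_recovered = rec, n_false = fp)
}

# Brute-force assignment oracle for strict linking: enumerate all partial
# one-to-one matchings over pairs satisfying both thresholds and return the
# one with the most links, breaking ties by smallest total score.
brute_force_links <- function(cells_t, cells_t1, patches_t, patches_t1,
                              params = tracking_params()) {
  n1 <- nrow(cells_t); n2 <- nrow(cells_t1)
  cand <- list()
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    d <- sqrt((cells_t$x[i] - cells_t1$x[j])^2 +
                (cells_t$y[i] - cells_t1$y[j])^2)
    if (d >= params$max_distance_px) next
    s <- appearance_score(patches_t[[i]], patches_t1[[j]],
                          params$rotation_step_deg)$score
    if (s <= params$appearance_threshold)
      cand[[length(cand) + 1L]] <- c(i, j, s)
  }
  if (length(cand) == 0L)
    return(data.frame(from = integer(0), to = integer(0), score = numeric(0)))
  cand <- do.call(rbind, cand)
  best <- NULL
  n_cand <- nrow(cand)
  recurse <- function(k, used_i, used_j, picked) {
    if (k > n_cand) {
      sc <- if (length(picked)) sum(cand[picked, 3]) else 0
      if (is.null(best) || length(picked) > length(best$picked) ||
          (length(picked) == length(best$picked) && sc < best$score))
        best <<- list(picked = picked, score = sc)
      return(invisible())
    }
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!(i %in% used_i) && !(j %in% used_j))
      recurse(k + 1L, c(used_i, i), c(used_j, j), c(picked, k))
    recurse(k + 1L, used_i, used_j, picked)
  }
  recurse(1L, integer(0), integer(0), integer(0))
  out <- data.frame(from = cand[best$picked, 1], to = cand[best$picked, 2],
                    score = cand[best$picked, 3])
  out[order(out$from), ]
}

# Linear-ramp patch at a given orientation: bilinear interpolation
# reproduces linear functions exactly, so rotating it through the grid
# leaves no interpolation residual at all.
ramp_patch <- function(angle_deg = 0, size = 32L) {
  ctr <- (size + 1) / 2
  th <- angle_deg * pi / 180
  g <- seq_len(size) - ctr
  dx <- outer(g, rep(1, size)); dy <- outer(rep(1, size), g)
  u <- cos(th) * dx + sin(th) * dy
  L <- sqrt(2) * (size / 2)
  list(values = (u + L) / (2 * L), mask = matrix(TRUE, size, size))
}

# Analytic smooth test patch: anisotropic Gaussian blob evaluated at a given
# rotation angle, plus an off-center satellite to break symmetry. Very
# smooth (scales ~6 px) so bilinear interpolation error stays tiny.
analytic_patch <- function(angle_deg = 0, size = 32L) {
  ctr <- (size + 1) / 2
  th <- angle_deg * pi / 180
  g <- seq_len(size) - ctr
  dx <- outer(g, rep(1, size)); dy <- outer(rep(1, size), g)
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  val <- exp(-(u^2 / (2 * 8^2) + v^2 / (2 * 5^2))) +
    0.5 * exp(-((u - 4)^2 + (v - 2)^2) / (2 * 6^2))
  val <- (val - min(val)) / (max(val) - min(val))
  list(values = val, mask = matrix(TRUE, size, size))
}
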