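# Expression statistics on tracked cells.
#
# The constitutive ECFP signal proxies plasmid copy number, so the ratio
# r(t) = venus(t) / ecfp(t) removes transfection-efficiency differences
# between cells; fold induction is r(t) relative to the cell's own
# pre-induction baseline. All spreads use the population SD convention
# (divide by N).

#' ECFP-normalized induction profiles
#'
#' Computes `r(t) = venus(t) / ecfp(t)` per tracked cell and frame, and fold
#' change `r(t) / mean(r over the first baseline_frames frames of the
#' track)`. Frames with (clamped-)zero ECFP are excluded and flagged;
#' tracks shorter than the baseline window, or with no usable baseline
#' frame, are excluded with a log entry in the `excluded` element.
#'
#' @param tracks data.frame from [track_field()] (needs `track_id`, `frame`,
#'   `venus`, `ecfp`).
#' @param baseline_frames number of leading frames of each track that define
#'   its pre-induction baseline (default 3, i.e. the first hour at 20-minute
#'   passes).
#' @return list: `profiles` (track_id, frame, r, fold), `cells` (track_id,
#'   baseline_mean, baseline_sd, peak_fold, n_frames), `excluded`
#'   (track_id, reason).
#' @export
normalize_profiles <- function(tracks, baseline_frames = 3L) {
  stopifnot(all(c("track_id", "frame", "venus", "ecfp") %in% names(tracks)))
  profs <- list(); cells <- list(); excl <- list()
  for (tid in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == tid, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) < baseline_frames) {
      excl[[length(excl) + 1L]] <- data.frame(track_id = tid,
                                              reason = "shorter than baseline window")
      next
    }
    usable <- tr$ecfp > 0
    r <- ifelse(usable, tr$venus / tr$ecfp, NA_real_)
    base_idx <- seq_len(baseline_frames)
    base_r <- r[base_idx][usable[base_idx]]
    if (length(base_r) == 0L || mean(base_r) <= 0) {
      excl[[length(excl) + 1L]] <- data.frame(track_id = tid,
                                              reason = "no usable baseline")
      next
    }
    bm <- mean(base_r)
    fold <- r / bm
    profs[[length(profs) + 1L]] <-
      data.frame(track_id = tid, frame = tr$frame, r = r, fold = fold)[usable, ]
    cells[[length(cells) + 1L]] <-
      data.frame(track_id = tid, baseline_mean = bm,
                 baseline_sd = pop_sd(base_r),
                 peak_fold = max(fold[usable]), n_frames = nrow(tr))
  }
  list(profiles = if (length(profs)) do.call(rbind, profs) else
         data.frame(track_id = integer(0), frame = integer(0),
                    r = numeric(0), fold = numeric(0)),
       cells = if (length(cells)) do.call(rbind, cells) else
         data.frame(track_id = integer(0), baseline_mean = numeric(0),
                    baseline_sd = numeric(0), peak_fold = numeric(0),
                    n_frames = integer(0)),
       excluded = if (length(excl)) do.call(rbind, excl) else
         data.frame(track_id = integer(0), reason = character(0)))
}

#' Responder classification by the 3-SD rule
#'
#' The threshold is the mean plus `sd_cutoff` population SDs of the signal
#' across all cells at the initial frame; a cell is a responder when its
#' signal exceeds the threshold at any later frame (`mode = "any"`) or at
#' the final frame only (`mode = "final"`).
#'
#' @param values data.frame with `track_id`, `frame`, and a signal column
#'   (raw Venus or the normalized ratio), named by `signal`.
#' @param signal name of the signal column.
#' @param mode comparison time: `"any"` later frame (default) or `"final"`.
#' @param sd_cutoff number of SDs above the initial mean (default 3).
#' @return list: `flags` (track_id, responder), `threshold`,
#'   `initial_mean`, `initial_sd`.
#' @export
classify_responders <- function(values, signal = "fold",
                                mode = c("any", "final"), sd_cutoff = 3) {
  mode <- match.arg(mode)
  stopifnot(all(c("track_id", "frame", signal) %in% names(values)))
  f0 <- min(values$frame)
  v0 <- values[[signal]][values$frame == f0]
  if (length(v0) < 2L)
    stopf("at least 2 cells are required at the initial frame")
  mu <- mean(v0); s <- pop_sd(v0)
  thr <- mu + sd_cutoff * s
  later <- values[values$frame > f0, , drop = FALSE]
  flags <- vapply(split(later, later$track_id), function(d) {
    if (nrow(d) == 0L) return(FALSE)
    if (mode == "final") d <- d[d$frame == max(d$frame), , drop = FALSE]
    any(d[[signal]] > thr)
  }, logical(1))
  all_ids <- unique(values$track_id)
  resp <- setNames(rep(FALSE, length(all_ids)), all_ids)
  resp[names(flags)] <- flags
  list(flags = data.frame(track_id = as.integer(names(resp)),
                          responder = unname(resp)),
       threshold = thr, initial_mean = mu, initial_sd = s)
}

#' Fold-change distribution over cells
#'
#' Bins peak fold changes below, between and above the two edges (default
#' under 3-fold, 3-50-fold, over 50-fold) and reports counts and fractions
#' (percent, one decimal).
#'
#' @param peak_folds numeric vector of per-cell peak fold changes.
#' @param bin_edges two increasing edges (default `c(3, 50)`).
#' @return data.frame: `bin`, `count`, `fraction_pct`.
#' @export
fold_distribution <- function(peak_folds, bin_edges = c(3, 50)) {
  peak_folds <- peak_folds[is.finite(peak_folds)]
  if (length(peak_folds) == 0L) stopf("no fold values supplied")
  stopifnot(length(bin_edges) == 2L, diff(bin_edges) > 0)
  n <- length(peak_folds)
  counts <- c(sum(peak_folds < bin_edges[1]),
              sum(peak_folds >= bin_edges[1] & peak_folds <= bin_edges[2]),
              sum(peak_folds > bin_edges[2]))
  data.frame(bin = c(sprintf("<%g", bin_edges[1]),
                     sprintf("[%g,%g]", bin_edges[1], bin_edges[2]),
                     sprintf(">%g", bin_edges[2])),
             count = counts,
             fraction_pct = round(100 * counts / n, 1))
}

#' Coefficient of variation of responder peak folds
#'
#' CV (population SD / mean, percent) of the peak normalized fold across
#' responding cells.
#'
#' @param peak_folds peak folds of the responder cells (length >= 2).
#' @return scalar CV in percent.
#' @export
responder_cv <- function(peak_folds) {
  peak_folds <- peak_folds[is.finite(peak_folds)]
  if (length(peak_folds) < 2L) stopf("at least 2 responders are required")
  100 * pop_sd(peak_folds) / mean(peak_folds)
}

#' Per-spot mean expression curves
#'
#' Averages single-cell channel totals per spot and frame, and the mean of
#' the per-spot means across spots per frame (the replicate mean curve).
#'
#' @param tracks data.frame with `track_id`, `frame`, `venus`, `ecfp`.
#' @param spot_map data.frame mapping `track_id` to `spot_id` (and
#'   optionally `construct`).
#' @return list: `spots` (spot_id, frame, mean_venus, mean_ecfp, n_cells),
#'   `mean_curve` (frame, mean_venus, mean_ecfp, n_spots).
#' @export
spot_curves <- function(tracks, spot_map) {
  stopifnot(all(c("track_id", "spot_id") %in% names(spot_map)))
  miss <- setdiff(tracks$track_id, spot_map$track_id)
  if (length(miss) > 0L)
    stopf("tracks without spot assignment: %s",
          paste(head(miss, 5), collapse = ", "))
  d <- merge(tracks, spot_map[, c("track_id", "spot_id")], by = "track_id")
  agg <- aggregate(cbind(venus, ecfp) ~ spot_id + frame, data = d, FUN = mean)
  cnt <- aggregate(track_id ~ spot_id + frame, data = d, FUN = length)
  spots <- merge(agg, cnt, by = c("spot_id", "frame"))
  names(spots) <- c("spot_id", "frame", "mean_venus", "mean_ecfp", "n_cells")
  spots <- spots[order(spots$spot_id, spots$frame), ]
  mc <- aggregate(cbind(mean_venus, mean_ecfp) ~ frame, data = spots, FUN = mean)
  ns <- aggregate(spot_id ~ frame, data = spots, FUN = length)
  mean_curve <- merge(mc, ns, by = "frame")
  names(mean_curve) <- c("frame", "mean_venus", "mean_ecfp", "n_spots")
  rownames(spots) <- rownames(mean_curve) <- NULL
  list(spots = spots, mean_curve = mean_curve)
}

#' Replicate subsampling: how many spots are enough?
#'
#' For each subset size `n`, draws `n_perm` subsets of the spot values
#' without replacement and records the distribution of subset means and
#' subset SDs. A subset size is adequate when the mean absolute deviation
#' between the subset SD and the population SD is at most
#' `criterion_factor` times the population SD.
#'
#' @param values per-spot values at one timepoint (>= 21 spots for the
#'   default range).
#' @param n_range subset sizes to evaluate (default 1..20).
#' @param n_perm permutations per size (default 1000).
#' @param seed RNG seed.
#' @param criterion_factor adequacy criterion factor (default 0.5).
#' @return list: `stats` (n, mean_of_means, sd_of_means, mean_sd,
#'   mean_abs_sd_dev, adequate), `min_adequate_n`, `population_sd`.
#' @export
replicate_subsampling <- function(values, n_range = 1:20, n_perm = 1000L,
                                  seed = 1L, criterion_factor = 0.5) {
  values <- values[is.finite(values)]
  if (max(n_range) > length(values))
    stopf("largest subset size (%d) exceeds the %d available spots",
          max(n_range), length(values))
  sd_pop <- pop_sd(values)
  with_seed(seed, {
    rows <- lapply(n_range, function(n) {
      means <- numeric(n_perm); sds <- numeric(n_perm)
      for (p in seq_len(n_perm)) {
        s <- values[sample.int(length(values), n)]
        means[p] <- mean(s)
        sds[p] <- pop_sd(s)
      }
      data.frame(n = n, mean_of_means = mean(means),
                 sd_of_means = pop_sd(means), mean_sd = mean(sds),
                 mean_abs_sd_dev = mean(abs(sds - sd_pop)))
    })
    stats <- do.call(rbind, rows)
    stats$adequate <- stats$mean_abs_sd_dev <= criterion_factor * sd_pop
    min_n <- if (any(stats$adequate)) min(stats$n[stats$adequate]) else NA_integer_
    list(stats = stats, min_adequate_n = min_n, population_sd = sd_pop)
  })
}

#' Segmentation/tracking error rate
#'
#' Percentage of evaluated cells with at least one segmentation or tracking
#' error, rounded to one decimal (e.g. 14 errors among 2340 cells give
#' 0.6%).
#'
#' @param error_flags logical vector, one entry per evaluated cell.
#' @return scalar percent.
#' @export
error_rate <- function(error_flags) {
  if (length(error_flags) == 0L) stopf("no cells were evaluated")
  round(100 * sum(error_flags) / length(error_flags), 1)
}

#' Score tracks against simulator ground truth
#'
#' Matches every tracked record to the nearest visible true cell within
#' `max_match_dist_px` of its centroid. A track's cell identity is the
#' majority matched cell; the track is flagged erroneous if any record is
#' unmatched (spurious segment) or matched to a different cell than the
#' majority (identity switch), or if another track has the same majority
#' cell (a split counts one error against each involved track beyond the
#' first).
#'
#' @param tracks data.frame from [track_field()].
#' @param truth the `truth` element of [simulate_field()] output.
#' @param max_match_dist_px matching radius (px).
#' @return logical vector of per-track error flags, named by track id.
#' @export
track_error_flags <- function(tracks, truth, max_match_dist_px = 6) {
  pos <- truth$positions
  ids <- sort(unique(tracks$track_id))
  assigned <- rep(NA_integer_, length(ids))
  flags <- setNames(rep(FALSE, length(ids)), ids)
  match_cell <- function(fr, x, y) {
    p <- pos[pos$frame == fr & pos$visible, , drop = FALSE]
    if (nrow(p) == 0L) return(NA_integer_)
    d2 <- (p$x - x)^2 + (p$y - y)^2
    i <- which.min(d2)
    if (d2[i] <= max_match_dist_px^2) p$cell[i] else NA_integer_
  }
  for (k in seq_along(ids)) {
    tr <- tracks[tracks$track_id == ids[k], , drop = FALSE]
    m <- mapply(match_cell, tr$frame, tr$x, tr$y)
    if (any(is.na(m))) { flags[k] <- TRUE; next }
    tab <- table(m)
    maj <- as.integer(names(tab)[which.max(tab)])
    assigned[k] <- maj
    if (any(m != maj)) flags[k] <- TRUE
  }
  # splits: a second track claiming an already-assigned cell is an error
  seen <- integer(0)
  for (k in seq_along(ids)) {
    a <- assigned[k]
    if (is.na(a)) next
    if (a %in% seen) flags[k] <- TRUE else seen <- c(seen, a)
  }
  flags
}
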