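# Two-phase single-cell tracking.
#
# Phase one (strict linking) joins cells in consecutive frames that are close
# in space and similar in appearance; phase two (flexible linking) closes
# gaps of up to five frames between track fragments using spatial proximity
# and the stability of the constitutive ECFP signal as the identity cue.

#' Tracking parameters
#'
#' @param max_distance_px strict-link centroid distance limit (10 px = 8 um
#'   at 0.8 um pixels).
#' @param appearance_threshold maximum accepted appearance score (mean
#'   squared difference of normalized patches; default 0.0155).
#' @param rotation_step_deg rotation search grid step for the appearance
#'   score (0..350 degrees).
#' @param ambiguity_margin relative margin of the "discrepant scores" rule:
#'   if a cell's second-best candidate scores within this relative margin of
#'   its best (`second <= (1 + margin) * best`), no link is made for that
#'   cell. Interpretive; exposed as a parameter.
#' @param intensity_sd_cutoff flexible-link rejection: candidate joins whose
#'   ECFP difference deviates more than this many SDs from the slide-wide
#'   candidate pool mean are removed (default 3).
#' @param max_gap_frames largest frame separation bridged by flexible
#'   linking (1..5; a separation of g frames skips g-1 time points).
#' @return a validated `tracking_params` list.
#' @export
tracking_params <- function(max_distance_px = 10,
                            appearance_threshold = 0.0155,
                            rotation_step_deg = 10,
                            ambiguity_margin = 0.2,
                            intensity_sd_cutoff = 3,
                            max_gap_frames = 5L) {
  p <- list(max_distance_px = max_distance_px,
            appearance_threshold = appearance_threshold,
            rotation_step_deg = rotation_step_deg,
            ambiguity_margin = ambiguity_margin,
            intensity_sd_cutoff = intensity_sd_cutoff,
            max_gap_frames = as.integer(max_gap_frames))
  stopifnot(p$max_distance_px > 0, p$appearance_threshold > 0,
            p$rotation_step_deg > 0, p$ambiguity_margin >= 0,
            p$max_gap_frames >= 1L, p$max_gap_frames <= 5L)
  class(p) <- "tracking_params"
  p
}

# --- rotation machinery -----------------------------------------------------
# Patch rotation uses precomputed bilinear resampling maps, one per grid
# angle, cached per (size, step). Angle 0 is the exact identity.

.rotation_cache <- new.env(parent = emptyenv())

rotation_maps <- function(size, step_deg) {
  key <- paste(size, step_deg, sep = "_")
  if (!is.null(.rotation_cache[[key]])) return(.rotation_cache[[key]])
  angles <- seq(0, 360 - step_deg, by = step_deg)
  ctr <- (size + 1) / 2
  gx <- rep(seq_len(size), size) - ctr
  gy <- rep(seq_len(size), each = size) - ctr
  maps <- lapply(angles, function(a) {
    th <- -a * pi / 180     # sample source = rotate target coords back
    sx <- ctr + cos(th) * gx - sin(th) * gy
    sy <- ctr + sin(th) * gx + cos(th) * gy
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    ok <- sx >= 1 & sx <= size & sy >= 1 & sy <= size
    ex <- ok & x0 == size; x0[ex] <- size - 1L; fx[ex] <- 1
    ey <- ok & y0 == size; y0[ey] <- size - 1L; fy[ey] <- 1
    i00 <- (y0 - 1) * size + x0
    list(angle = a, ok = ok, i00 = i00[ok], size = size,
         w00 = ((1 - fx) * (1 - fy))[ok], w10 = (fx * (1 - fy))[ok],
         w01 = ((1 - fx) * fy)[ok], w11 = (fx * fy)[ok])
  })
  .rotation_cache[[key]] <- maps
  maps
}

map_valid <- function(map) matrix(map$ok, map$size, map$size)

rotate_by_map <- function(m, map) {
  out <- numeric(map$size^2)
  v <- map$w00 * m[map$i00] + map$w10 * m[map$i00 + 1] +
    map$w01 * m[map$i00 + map$size] + map$w11 * m[map$i00 + map$size + 1]
  out[map$ok] <- v
  matrix(out, map$size, map$size)
}

#' Rotate an appearance patch
#'
#' Rotates a patch (values and mask) about its center by an arbitrary angle
#' using bilinear resampling; pixels rotated in from outside are 0.
#'
#' @param patch `list(values, mask)` or a bare matrix.
#' @param angle_deg rotation angle, degrees.
#' @return a `list(values, mask)` patch.
#' @export
rotate_patch <- function(patch, angle_deg) {
  p <- as_patch(patch)
  angle_deg <- angle_deg %% 360
  if (angle_deg == 0) return(p)
  size <- nrow(p$values)
  map <- single_rotation_map(size, angle_deg)
  list(values = rotate_by_map(p$values, map),
       mask = rotate_by_map(p$mask * 1, map) >= 0.5)
}

single_rotation_map <- function(size, angle_deg) {
  ctr <- (size + 1) / 2
  gx <- rep(seq_len(size), size) - ctr
  gy <- rep(seq_len(size), each = size) - ctr
  th <- -angle_deg * pi / 180
  sx <- ctr + cos(th) * gx - sin(th) * gy
  sy <- ctr + sin(th) * gx + cos(th) * gy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  ok <- sx >= 1 & sx <= size & sy >= 1 & sy <= size
  ex <- ok & x0 == size; x0[ex] <- size - 1L; fx[ex] <- 1
  ey <- ok & y0 == size; y0[ey] <- size - 1L; fy[ey] <- 1
  i00 <- (y0 - 1) * size + x0
  list(angle = angle_deg, ok = ok, i00 = i00[ok], size = size,
       w00 = ((1 - fx) * (1 - fy))[ok], w10 = (fx * (1 - fy))[ok],
       w01 = ((1 - fx) * fy)[ok], w11 = (fx * fy)[ok])
}

as_patch <- function(p) {
  if (is.list(p) && !is.null(p$values)) return(p)
  if (is.matrix(p)) return(list(values = p, mask = matrix(TRUE, nrow(p), ncol(p))))
  stopf("a patch must be a matrix or list(values, mask)")
}

#' Appearance score between two cell patches
#'
#' The score is the average squared difference between the two normalized
#' (values in `[0, 1]`) patches, minimized over a grid of relative rotations.
#' Differences are averaged over the union of the two nucleus masks, so
#' shape mismatch is penalized. Lower is more similar; 0 means identical.
#'
#' @param patch_a,patch_b `list(values, mask)` patches from
#'   [segment_frame()], or bare matrices (mask = all pixels).
#' @param rotation_step_deg rotation grid step (degrees).
#' @return list with `score` (minimum over rotations) and `angle` (the
#'   minimizing rotation of `patch_b`, degrees).
#' @export
appearance_score <- function(patch_a, patch_b, rotation_step_deg = 10) {
  a <- as_patch(patch_a)
  b <- as_patch(patch_b)
  if (!all(dim(a$values) == dim(b$values)))
    stopf("patches must have the same size")
  maps <- rotation_maps(nrow(a$values), rotation_step_deg)
  best <- Inf; best_angle <- 0
  for (map in maps) {
    vb <- rotate_by_map(b$values, map)
    mb <- rotate_by_map(b$mask * 1, map) >= 0.5
    u <- (a$mask | mb) & map_valid(map)
    nu <- sum(u)
    if (nu == 0L) next
    s <- sum((a$values[u] - vb[u])^2) / nu
    if (s < best) { best <- s; best_angle <- map$angle }
  }
  if (!is.finite(best)) { best <- 0; best_angle <- 0 }
  list(score = best, angle = best_angle)
}

# Scores of candidate pairs (i in records_t, j in records_t1), with rotated
# versions of each target patch computed once.
score_candidates <- function(pairs, patches_t, patches_t1, step_deg) {
  if (nrow(pairs) == 0L)
    return(cbind(pairs, score = numeric(0), angle = numeric(0)))
  need <- unique(pairs$to)
  rot <- new.env(parent = emptyenv())
  maps <- NULL
  scores <- numeric(nrow(pairs)); angles <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$from[r]; j <- pairs$to[r]
    a <- as_patch(patches_t[[i]])
    if (is.null(maps)) maps <- rotation_maps(nrow(a$values), step_deg)
    kj <- as.character(j)
    if (is.null(rot[[kj]])) {
      b <- as_patch(patches_t1[[j]])
      rot[[kj]] <- lapply(maps, function(map)
        list(v = rotate_by_map(b$values, map),
             m = rotate_by_map(b$mask * 1, map) >= 0.5, angle = map$angle,
             valid = map_valid(map)))
    }
    best <- Inf; best_angle <- 0
    for (rb in rot[[kj]]) {
      u <- (a$mask | rb$m) & rb$valid
      nu <- sum(u)
      if (nu == 0L) next
      s <- sum((a$values[u] - rb$v[u])^2) / nu
      if (s < best) { best <- s; best_angle <- rb$angle }
    }
    if (!is.finite(best)) { best <- 0; best_angle <- 0 }
    scores[r] <- best; angles[r] <- best_angle
  }
  cbind(pairs, score = scores, angle = angles)
}

#' Strict linking of cells between consecutive frames
#'
#' Candidate links require a centroid distance below `max_distance_px` and
#' an appearance score at or below `appearance_threshold`. If a cell's best
#' and second-best candidate scores are within the relative
#' `ambiguity_margin` of each other, the scores are considered discrepant
#' and that cell is not linked. Remaining conflicts are resolved greedily in
#' order of increasing score, each cell used at most once per side, giving a
#' partial one-to-one matching.
#'
#' @param cells_t,cells_t1 data.frames with columns `x`, `y` (rows index
#'   cells in frames t and t+1).
#' @param patches_t,patches_t1 parallel lists of appearance patches.
#' @param params a [tracking_params()].
#' @return data.frame of links: `from`, `to` (row indices), `score`, `angle`.
#' @export
strict_link <- function(cells_t, cells_t1, patches_t, patches_t1,
                        params = tracking_params()) {
  n1 <- nrow(cells_t); n2 <- nrow(cells_t1)
  empty <- data.frame(from = integer(0), to = integer(0),
                      score = numeric(0), angle = numeric(0))
  if (n1 == 0L || n2 == 0L) return(empty)
  dx <- outer(cells_t$x, cells_t1$x, "-")
  dy <- outer(cells_t$y, cells_t1$y, "-")
  close <- which(dx^2 + dy^2 < params$max_distance_px^2, arr.ind = TRUE)
  if (nrow(close) == 0L) return(empty)
  pairs <- data.frame(from = close[, 1], to = close[, 2])
  pairs <- score_candidates(pairs, patches_t, patches_t1,
                            params$rotation_step_deg)
  pairs <- pairs[pairs$score <= params$appearance_threshold, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)
  # discrepant-scores rule, applied per source cell
  drop_from <- vapply(split(pairs$score, pairs$from), function(s) {
    if (length(s) < 2L) return(FALSE)
    s <- sort(s)
    s[2] <= (1 + params$ambiguity_margin) * s[1]
  }, logical(1))
  bad <- as.integer(names(drop_from))[drop_from]
  pairs <- pairs[!pairs$from %in% bad, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)
  # greedy best-score conflict resolution
  pairs <- pairs[order(pairs$score, pairs$from, pairs$to), , drop = FALSE]
  used_from <- logical(n1); used_to <- logical(n2)
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    f <- pairs$from[r]; t2 <- pairs$to[r]
    if (!used_from[f] && !used_to[t2]) {
      keep[r] <- TRUE
      used_from[f] <- TRUE; used_to[t2] <- TRUE
    }
  }
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Build track fragments (chains of record ids) from per-transition strict
# links. `records` must have columns frame and a row id implied by position.
fragments_from_links <- function(records, links_by_transition) {
  succ <- rep(NA_integer_, nrow(records))
  has_pred <- logical(nrow(records))
  for (ln in links_by_transition) {
    if (nrow(ln) == 0L) next
    succ[ln$from_rec] <- ln$to_rec
    has_pred[ln$to_rec] <- TRUE
  }
  starts <- which(!has_pred)
  lapply(starts, function(s) {
    chain <- s
    while (!is.na(succ[chain[length(chain)]]))
      chain <- c(chain, succ[chain[length(chain)]])
    chain
  })
}

#' Flexible linking: gap closing between track fragments
#'
#' For each gap `g = 1..max_gap_frames` in turn, candidate joins are
#' fragment-end to fragment-start pairs separated by exactly `g` frames and
#' within `g * max_distance_px`. The absolute ECFP intensity differences of
#' all candidates are pooled slide-wide; candidates deviating more than
#' `intensity_sd_cutoff` SDs from the pool mean are removed, and the
#' remaining joins are accepted greedily in order of increasing intensity
#' difference, each fragment end and start used once. Joined fragments
#' merge, annotated with the number of skipped frames (`g - 1`).
#'
#' @param fragments list of integer vectors of record row indices (from
#'   strict linking), each ordered by frame.
#' @param records data.frame with columns `frame`, `x`, `y`, `ecfp`.
#' @param params a [tracking_params()].
#' @return list with `fragments` (merged chains) and `joins` (data.frame:
#'   from_rec, to_rec, gap_frames, ecfp_diff).
#' @export
flexible_link <- function(fragments, records, params = tracking_params()) {
  joins <- data.frame(from_rec = integer(0), to_rec = integer(0),
                      gap_frames = integer(0), ecfp_diff = numeric(0))
  for (g in seq_len(params$max_gap_frames)) {
    if (length(fragments) < 2L) break
    ends <- vapply(fragments, function(ch) ch[length(ch)], integer(1))
    starts <- vapply(fragments, function(ch) ch[1], integer(1))
    ef <- records$frame[ends]; sf <- records$frame[starts]
    cand <- NULL
    for (a in seq_along(fragments)) {
      hit <- which(sf - ef[a] == g)
      hit <- hit[hit != a]
      if (length(hit) == 0L) next
      d <- sqrt((records$x[ends[a]] - records$x[starts[hit]])^2 +
                (records$y[ends[a]] - records$y[starts[hit]])^2)
      ok <- d <= g * params$max_distance_px
      if (any(ok))
        cand <- rbind(cand, data.frame(fa = a, fb = hit[ok], dist = d[ok]))
    }
    if (is.null(cand) || nrow(cand) == 0L) next
    cand$ecfp_diff <- abs(records$ecfp[ends[cand$fa]] -
                          records$ecfp[starts[cand$fb]])
    if (nrow(cand) >= 2L) {
      mu <- mean(cand$ecfp_diff)
      sdd <- pop_sd(cand$ecfp_diff)
      if (sdd > 0)
        cand <- cand[abs(cand$ecfp_diff - mu) <=
                     params$intensity_sd_cutoff * sdd, , drop = FALSE]
    }
    if (nrow(cand) == 0L) next
    cand <- cand[order(cand$ecfp_diff, cand$fa, cand$fb), , drop = FALSE]
    used_end <- logical(length(fragments))
    used_start <- logical(length(fragments))
    merge_into <- seq_along(fragments)
    root <- function(i) { while (merge_into[i] != i) i <- merge_into[i]; i }
    accepted <- NULL
    for (r in seq_len(nrow(cand))) {
      a <- cand$fa[r]; b <- cand$fb[r]
      if (used_end[a] || used_start[b]) next
      if (root(a) == root(b)) next   # would close a loop
      used_end[a] <- TRUE; used_start[b] <- TRUE
      merge_into[root(b)] <- root(a)
      accepted <- rbind(accepted, cand[r, ])
      joins <- rbind(joins, data.frame(from_rec = ends[a], to_rec = starts[b],
                                       gap_frames = g - 1L,
                                       ecfp_diff = cand$ecfp_diff[r]))
    }
    if (is.null(accepted)) next
    # rebuild fragments after this gap level
    succ_frag <- rep(NA_integer_, length(fragments))
    succ_frag[accepted$fa] <- accepted$fb
    is_start <- rep(TRUE, length(fragments))
    is_start[accepted$fb] <- FALSE
    new_frags <- list()
    for (a in which(is_start)) {
      chain <- fragments[[a]]
      nxt <- succ_frag[a]
      while (!is.na(nxt)) {
        chain <- c(chain, fragments[[nxt]])
        nxt <- succ_frag[nxt]
      }
      new_frags[[length(new_frags) + 1L]] <- chain
    }
    fragments <- new_frags
  }
  list(fragments = fragments, joins = joins)
}

#' Track all cells of one field
#'
#' Runs strict linking over every pair of consecutive frames, chains the
#' links into fragments, then closes gaps with flexible linking. Fields are
#' independent: no state is shared across fields, so fields may be
#' processed in any order with identical results.
#'
#' @param records data.frame of all cell records of the field, with columns
#'   `frame`, `label`, `x`, `y`, `area_px2`, `venus`, `ecfp` (one row per
#'   segmented cell; row order defines record ids).
#' @param patches list of appearance patches parallel to `records` rows.
#' @param params a [tracking_params()].
#' @return data.frame of tracked records: `track_id`, `frame`, plus all
#'   record columns, `gap_before` (frames skipped by flexible linking
#'   before this record) and `link_type` (`start`, `strict`, `flexible`).
#' @export
track_field <- function(records, patches, params = tracking_params()) {
  if (nrow(records) == 0L)
    return(cbind(data.frame(track_id = integer(0)), records,
                 data.frame(gap_before = integer(0), link_type = character(0))))
  frames <- sort(unique(records$frame))
  by_frame <- split(seq_len(nrow(records)), records$frame)
  links <- list()
  strict_to <- rep(FALSE, nrow(records))
  for (k in seq_along(frames)) {
    if (k == length(frames)) break
    if (frames[k + 1] - frames[k] != 1) next
    it <- by_frame[[as.character(frames[k])]]
    it1 <- by_frame[[as.character(frames[k + 1])]]
    ln <- strict_link(records[it, , drop = FALSE], records[it1, , drop = FALSE],
                      patches[it], patches[it1], params)
    if (nrow(ln) > 0L) {
      ln$from_rec <- it[ln$from]
      ln$to_rec <- it1[ln$to]
      strict_to[ln$to_rec] <- TRUE
      links[[length(links) + 1L]] <- ln
    }
  }
  frags <- fragments_from_links(records, links)
  fl <- flexible_link(frags, records, params)
  # order tracks by first frame then position for determinism
  firsts <- vapply(fl$fragments, function(ch) ch[1], integer(1))
  ord <- order(records$frame[firsts], records$x[firsts], records$y[firsts])
  out <- list()
  join_to <- fl$joins$to_rec
  for (ti in seq_along(ord)) {
    ch <- fl$fragments[[ord[ti]]]
    df <- records[ch, , drop = FALSE]
    df$track_id <- ti
    gaps <- c(0L, pmax(diff(records$frame[ch]) - 1L, 0L))
    df$gap_before <- gaps
    lt <- ifelse(seq_along(ch) == 1L, "start",
                 ifelse(ch %in% join_to, "flexible", "strict"))
    # a record can be both a fragment start and a flexible-join target
    lt[ch %in% join_to] <- "flexible"
    lt[1] <- if (ch[1] %in% join_to) "flexible" else "start"
    df$link_type <- lt
    out[[ti]] <- df
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("track_id", setdiff(names(out), "track_id"))]
}
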