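# End-to-end pipeline: simulate (optional) -> segment -> track -> analyze.

#' Segment and quantify every frame of a field
#'
#' Runs [segment_frame()] on the segmentation channel of each frame (the
#' constitutive ECFP channel by default, since it is present in every cell
#' regardless of induction state), then quantifies background-subtracted
#' totals of both channels over the resulting masks.
#'
#' @param field a `field_stack`.
#' @param params a [segmentation_params()].
#' @param segment_on channel used to segment (`"ecfp"` or `"venus"`).
#' @return list: `records` (data.frame: frame, label, x, y, area_px2,
#'   venus, ecfp, clamp flags), `patches` (parallel list), `masks` (list of
#'   per-frame label matrices).
#' @export
segment_field <- function(field, params = segmentation_params(),
                          segment_on = c("ecfp", "venus")) {
  segment_on <- match.arg(segment_on)
  recs <- list(); patches <- list(); masks <- vector("list", field$n_frames)
  for (t in seq_len(field$n_frames)) {
    img <- field[[segment_on]][[t]]
    seg <- segment_frame(img, params)
    masks[[t]] <- seg$labels
    if (nrow(seg$cells) == 0L) next
    q <- quantify_and_subtract_background(
      seg$labels,
      list(venus = field$venus[[t]], ecfp = field$ecfp[[t]]),
      background_fraction = params$background_fraction)
    df <- merge(seg$cells, q, by = "label")
    df <- df[, c("label", "x", "y", "area_px2.x", "venus", "ecfp",
                 "venus_clamped", "ecfp_clamped")]
    names(df)[names(df) == "area_px2.x"] <- "area_px2"
    df <- cbind(data.frame(frame = t), df)
    df <- df[order(df$label), , drop = FALSE]
    recs[[length(recs) + 1L]] <- df
    patches <- c(patches, seg$patches[df$label])
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(frame = integer(0), label = integer(0), x = numeric(0),
               y = numeric(0), area_px2 = numeric(0), venus = numeric(0),
               ecfp = numeric(0), venus_clamped = logical(0),
               ecfp_clamped = logical(0))
  rownames(records) <- NULL
  list(records = records, patches = patches, masks = masks)
}

#' Pipeline configuration
#'
#' @param n_fields number of fields (spots) to process.
#' @param simulation a [simulation_config()] used to generate each field
#'   (per-field seeds are derived from it); `NULL` requires `field_paths`.
#' @param field_paths optional data.frame with `venus` and `ecfp` TIFF paths
#'   per field, used instead of simulation.
#' @param segmentation a [segmentation_params()].
#' @param tracking a [tracking_params()].
#' @param baseline_frames,responder_mode,fold_bin_edges analysis options.
#' @param seed master seed; field f derives seed `seed + 1000 * f` for its
#'   simulation.
#' @param out_dir optional output directory for per-stage artifacts.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_fields = 1L,
                            simulation = simulation_config(),
                            field_paths = NULL,
                            segmentation = segmentation_params(),
                            tracking = tracking_params(),
                            baseline_frames = 3L,
                            responder_mode = "any",
                            fold_bin_edges = c(3, 50),
                            seed = 1L,
                            out_dir = NULL) {
  cfg <- list(n_fields = as.integer(n_fields), simulation = simulation,
              field_paths = field_paths, segmentation = segmentation,
              tracking = tracking, baseline_frames = as.integer(baseline_frames),
              responder_mode = responder_mode,
              fold_bin_edges = fold_bin_edges, seed = as.integer(seed),
              out_dir = out_dir)
  if (is.null(cfg$simulation) && is.null(cfg$field_paths))
    stopf("either a simulation config or per-field channel paths are required")
  if (!is.null(cfg$field_paths)) {
    if (!all(c("venus", "ecfp") %in% names(cfg$field_paths)))
      stopf("field_paths must have 'venus' and 'ecfp' columns")
    missing <- !file.exists(unlist(cfg$field_paths[, c("venus", "ecfp")]))
    if (any(missing)) stopf("missing channel files in field_paths")
    cfg$n_fields <- nrow(cfg$field_paths)
  }
  if (cfg$n_fields < 1L) stopf("n_fields must be >= 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline
#'
#' For each field: simulate (or load), segment, quantify and track; then
#' pool tracks across fields and compute induction statistics (normalized
#' profiles, responder calling, fold-change bins) and, when ground truth is
#' available, the segmentation/tracking error rate. Fields carry no shared
#' state, so processing order does not affect results.
#'
#' @param config a [pipeline_config()].
#' @return a summary list (also written as JSON to `out_dir` when set) with
#'   per-stage counts, responder statistics, the fold-change distribution
#'   and the QC error rate; `tracks` holds the pooled track table.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  all_tracks <- list()
  spot_map <- list()
  per_field <- list()
  truth_flags <- logical(0)
  n_true_cells <- 0L
  next_track <- 0L
  for (f in seq_len(config$n_fields)) {
    if (!is.null(config$field_paths)) {
      field <- read_field_stack(config$field_paths$venus[f],
                                config$field_paths$ecfp[f])
    } else {
      sim <- config$simulation
      sim$rng_seed <- config$seed + 1000L * f
      field <- simulate_field(sim)
    }
    seg <- segment_field(field, config$segmentation)
    tracks <- track_field(seg$records, seg$patches, config$tracking)
    per_field[[f]] <- data.frame(
      field = f,
      n_records = nrow(seg$records),
      n_tracks = if (nrow(tracks)) max(tracks$track_id) else 0L,
      mean_cells_per_frame = if (nrow(seg$records))
        nrow(seg$records) / field$n_frames else 0)
    if (!is.null(field$truth) && nrow(tracks) > 0L) {
      fl <- track_error_flags(tracks, field$truth)
      truth_flags <- c(truth_flags, fl)
      n_true_cells <- n_true_cells + nrow(field$truth$cells)
    }
    if (nrow(tracks) > 0L) {
      tracks$track_id <- tracks$track_id + next_track
      tracks$field <- f
      next_track <- max(tracks$track_id)
      all_tracks[[f]] <- tracks
      spot_map[[f]] <- data.frame(track_id = unique(tracks$track_id),
                                  spot_id = f)
    }
  }
  tracks <- do.call(rbind, all_tracks)
  norm <- normalize_profiles(tracks, config$baseline_frames)
  resp <- classify_responders(norm$profiles, signal = "fold",
                              mode = config$responder_mode)
  folds <- fold_distribution(norm$cells$peak_fold, config$fold_bin_edges)
  resp_peaks <- norm$cells$peak_fold[
    norm$cells$track_id %in% resp$flags$track_id[resp$flags$responder]]
  summary <- list(
    n_fields = config$n_fields,
    per_field = do.call(rbind, per_field),
    n_tracks = length(unique(tracks$track_id)),
    n_profiled = nrow(norm$cells),
    responder_fraction = mean(resp$flags$responder),
    responder_threshold = resp$threshold,
    responder_cv_pct = if (length(resp_peaks) >= 2)
      responder_cv(resp_peaks) else NA_real_,
    median_peak_fold = median(norm$cells$peak_fold),
    fold_distribution = folds,
    qc_error_rate_pct = if (length(truth_flags))
      error_rate(truth_flags) else NA_real_,
    n_cells_evaluated = length(truth_flags)
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(tracks, file.path(config$out_dir, "tracks.csv"),
              row.names = FALSE)
    jsonlite::write_json(summary[setdiff(names(summary), "per_field")],
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  summary$tracks <- tracks
  summary$profiles <- norm
  summary$spot_map <- do.call(rbind, spot_map)
  invisible(summary)
}
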