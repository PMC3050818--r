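# File formats: multi-page TIFF stacks, label masks, tabular exports.
# Images travel as integer camera counts (0..65535) and are stored as 16-bit
# TIFF pages in frame (time) order, one file per channel per field.

counts_to_tiff <- function(frames) lapply(frames, function(f) f / 65535)

tiff_to_counts <- function(pages) {
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate extra samples
    matrix(as.integer(round(p * 65535)), nrow(p), ncol(p))
  })
}

#' Write a simulated field to disk
#'
#' Writes the two channel stacks as 16-bit multi-page TIFFs
#' (`<prefix>_venus.tif`, `<prefix>_ecfp.tif`), the ground-truth label masks
#' (`<prefix>_mask.tif`), the per-cell parameters and positions as CSV, and
#' a YAML echo of the configuration.
#'
#' @param field a `field_stack` from [simulate_field()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default `"field"`).
#' @return invisibly, the named vector of written paths.
#' @export
write_field_stack <- function(field, dir, prefix = "field") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(venus = file.path(dir, paste0(prefix, "_venus.tif")),
             ecfp = file.path(dir, paste0(prefix, "_ecfp.tif")))
  tiff::writeTIFF(counts_to_tiff(field$venus), paths["venus"],
                  bits.per.sample = 16L)
  tiff::writeTIFF(counts_to_tiff(field$ecfp), paths["ecfp"],
                  bits.per.sample = 16L)
  if (!is.null(field$truth)) {
    paths["mask"] <- file.path(dir, paste0(prefix, "_mask.tif"))
    tiff::writeTIFF(counts_to_tiff(field$truth$masks), paths["mask"],
                    bits.per.sample = 16L)
    paths["cells"] <- file.path(dir, paste0(prefix, "_cells.csv"))
    write.csv(field$truth$cells, paths["cells"], row.names = FALSE)
    paths["positions"] <- file.path(dir, paste0(prefix, "_positions.csv"))
    write.csv(field$truth$positions, paths["positions"], row.names = FALSE)
    paths["config"] <- file.path(dir, paste0(prefix, "_config.yaml"))
    cfg <- field$truth$config
    yaml::write_yaml(unclass(cfg), paths["config"])
  }
  invisible(paths)
}

#' Read a two-channel field stack from multi-page TIFFs
#'
#' Pages are loaded in file order as time. The two channels must agree in
#' frame count and frame dimensions.
#'
#' @param venus_path,ecfp_path paths to the per-channel multi-page TIFFs.
#' @param frame_interval_min minutes between frames (timestamps metadata).
#' @param pixel_size_um pixel calibration metadata.
#' @return a `field_stack` list (without ground truth).
#' @export
read_field_stack <- function(venus_path, ecfp_path, frame_interval_min = 20,
                             pixel_size_um = 0.8) {
  venus <- tiff_to_counts(tiff::readTIFF(venus_path, all = TRUE))
  ecfp <- tiff_to_counts(tiff::readTIFF(ecfp_path, all = TRUE))
  if (length(venus) != length(ecfp))
    stopf("frame count mismatch: %d Venus pages vs %d ECFP pages",
          length(venus), length(ecfp))
  if (length(venus) > 0L && !all(dim(venus[[1]]) == dim(ecfp[[1]])))
    stopf("frame dimensions differ between channels")
  structure(list(venus = venus, ecfp = ecfp, n_frames = length(venus),
                 frame_interval_min = frame_interval_min,
                 pixel_size_um = pixel_size_um,
                 timestamps = (seq_along(venus) - 1) * frame_interval_min,
                 truth = NULL),
            class = "field_stack")
}

#' Read ground-truth label masks written by [write_field_stack()]
#'
#' @param mask_path multi-page label TIFF.
#' @return list of integer label matrices.
#' @export
read_label_masks <- function(mask_path) {
  tiff_to_counts(tiff::readTIFF(mask_path, all = TRUE))
}
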