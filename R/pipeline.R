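#' Run the full CP-VI detection pipeline on one recording
#'
#' Decimates to 40 Hz if needed, computes the smoothed sliding-window
#' Sample Entropy series of the chosen channel, partitions the recording
#' into segments, aggregates the per-segment feature and flags CP-VI
#' segments by percent change from the evolving personal baseline.
#' Defaults are the flow-channel operating point that performed best in
#' validation (`m = 2`, `r = 0.2`, `Th = 25%`, max feature); the
#' corresponding pressure-channel operating point is `m = 4`, `r = 0.2`,
#' `Th = 30%`.
#'
#' @param rec A [waveform_recording()] (any integer multiple of 40 Hz).
#' @param channel `"flow"` (default) or `"paw"`.
#' @param feature `"max"` (default) or `"mean"`.
#' @param m,r Sample Entropy settings (embedding dimension, tolerance as
#'   a multiple of the window SD).
#' @param th Detection threshold on percent change (percent).
#' @param segment_minutes Segment duration (default 15).
#' @param params An [se_params()] overriding `m`/`r` if supplied.
#' @param min_defined Minimum defined SE points per evaluable segment.
#' @param baseline_init_k See [detect_cpvi()].
#' @return A `cpvi_detections` data.frame (one row per segment).
#' @examples
#' sim <- simulate_recording(sim_config(duration_min = 15, seed = 7))
#' det <- detect_recording(sim$recording)
#' det$cpvi
#' @export
detect_recording <- function(rec, channel = c("flow", "paw"),
                             feature = c("max", "mean"), m = 2L, r = 0.2,
                             th = 25, segment_minutes = 15,
                             params = NULL, min_defined = 10L,
                             baseline_init_k = 1L) {
  channel <- match.arg(channel)
  feature <- match.arg(feature)
  if (rec$rate != 40) rec <- decimate_to_40hz(rec)
  if (is.null(params)) params <- se_params(m = m, r_factor = r)
  series <- se_sliding_series(rec, params = params, channel = channel)
  segments <- partition_segments(rec, segment_minutes)
  feats <- segment_features(series, segments, kind = feature,
                            min_defined = min_defined)
  detect_cpvi(feats, th = th, baseline_init_k = baseline_init_k)
}

#' Export mean-MCC surfaces from a grid result
#'
#' Writes, for every (channel, feature, r) slice of the grid result, the
#' m x Th matrix of mean MCC as a CSV, and a composite heat-map image of
#' all slices.
#'
#' @param result A `cpvi_grid_result`.
#' @param dir Output directory (created if missing).
#' @param image Also write `mcc_surfaces.png` (default `TRUE`).
#' @return Invisibly, the paths written.
#' @export
export_mcc_surface <- function(result, dir, image = TRUE) {
  stopifnot(inherits(result, "cpvi_grid_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cb <- result$combos
  paths <- character(0)
  slices <- unique(cb[, c("channel", "feature", "r")])
  for (i in seq_len(nrow(slices))) {
    sl <- cb[cb$channel == slices$channel[i] &
             cb$feature == slices$feature[i] & cb$r == slices$r[i], ]
    mat <- stats::xtabs(mean_mcc ~ m + th, data = sl)
    p <- file.path(dir, sprintf("mcc_%s_%s_r%s.csv", slices$channel[i],
                                slices$feature[i], slices$r[i]))
    utils::write.csv(as.data.frame.matrix(mat), p)
    paths <- c(paths, p)
  }
  if (image) {
    p <- file.path(dir, "mcc_surfaces.png")
    grDevices::png(p, width = 300 * nrow(slices), height = 320)
    op <- graphics::par(mfrow = c(1, nrow(slices)), mar = c(4, 4, 2, 1))
    on.exit({ graphics::par(op); grDevices::dev.off() })
    for (i in seq_len(nrow(slices))) {
      sl <- cb[cb$channel == slices$channel[i] &
               cb$feature == slices$feature[i] & cb$r == slices$r[i], ]
      mat <- stats::xtabs(mean_mcc ~ m + th, data = sl)
      graphics::image(as.numeric(rownames(mat)),
                      as.numeric(colnames(mat)), unclass(mat),
                      xlab = "m", ylab = "Th (%)",
                      main = sprintf("%s %s r=%s", slices$channel[i],
                                     slices$feature[i], slices$r[i]))
    }
    paths <- c(paths, p)
  }
  invisible(paths)
}
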