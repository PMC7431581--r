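#' Read a two-channel ventilator recording
#'
#' Reads airway flow and airway pressure from CSV/TSV (columns matching
#' `time`, `flow`, `paw` by name prefix, e.g. `time_s`, `flow_lpm`,
#' `paw_cmh2o`) or from EDF (channels selected by case-insensitive label
#' substring). Sampling uniformity is verified: the maximum deviation of
#' the time column from an ideal uniform grid must be below half a sample
#' period, otherwise a sampling error is raised. Recordings with missing
#' values are rejected.
#'
#' @param path Path to a `.csv`, `.tsv` or `.edf` file.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"edf"`.
#' @param mode Ventilation mode to attach (`"PSV"`, `"ACV"`, `"UNKNOWN"`).
#' @param subject_id Subject identifier to attach (default: file stem).
#' @return A [waveform_recording()].
#' @seealso [write_recording_csv()], [decimate_to_40hz()]
#' @export
read_recording <- function(path, format = c("auto", "csv", "tsv", "edf"),
                           mode = "UNKNOWN", subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", edf = "edf",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format=", call. = FALSE))
  }
  if (is.null(subject_id)) {
    subject_id <- tools::file_path_sans_ext(basename(path))
  }
  if (format == "edf") {
    return(read_edf_recording(path, mode = mode, subject_id = subject_id))
  }
  sep <- if (format == "tsv") "\t" else ","
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE)
  if (nrow(dt) == 0L) stop("empty recording file: ", path, call. = FALSE)
  pick <- function(prefix) {
    hit <- grep(paste0("^", prefix), names(dt), ignore.case = TRUE)
    if (length(hit) == 0L) {
      stop("format error: no column matching '", prefix, "' in ", path,
           call. = FALSE)
    }
    dt[[hit[1L]]]
  }
  tm <- pick("time"); flow <- pick("flow"); paw <- pick("paw")
  if (anyNA(tm) || anyNA(flow) || anyNA(paw)) {
    stop("recording contains missing values; gaps are rejected",
         call. = FALSE)
  }
  if (length(tm) < 2L) stop("recording too short", call. = FALSE)
  dt_med <- stats::median(diff(tm))
  if (!is.finite(dt_med) || dt_med <= 0) {
    stop("sampling error: non-increasing time column", call. = FALSE)
  }
  rate <- 1 / dt_med
  ideal <- tm[1L] + (seq_along(tm) - 1L) * dt_med
  if (max(abs(tm - ideal)) >= dt_med / 2) {
    stop("sampling error: non-uniform timestamps (max jitter >= half a ",
         "sample period)", call. = FALSE)
  }
  waveform_recording(flow = flow, paw = paw, rate = rate,
                     start_time = tm[1L], subject_id = subject_id,
                     mode = mode)
}

#' Write a recording to CSV
#'
#' Columns `time_s`, `flow_lpm`, `paw_cmh2o`. Doubles are written with 17
#' significant digits so that reading the file back reproduces the samples
#' bit-exactly.
#'
#' @param rec A [waveform_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "waveform_recording"))
  n <- length(rec$flow)
  tm <- rec$start_time + (seq_len(n) - 1) / rec$rate
  dt <- data.table::data.table(
    time_s = sprintf("%.17g", tm),
    flow_lpm = sprintf("%.17g", rec$flow),
    paw_cmh2o = sprintf("%.17g", rec$paw))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Decimate a recording to 40 Hz
#'
#' Anti-aliased, zero-phase decimation: a linear-phase FIR low-pass
#' (Hamming-windowed, cutoff 16 Hz = 0.8 x the 20 Hz output Nyquist)
#' applied centred so breath landmarks keep their timestamps, followed by
#' integer downsampling. A 40 Hz input is returned unchanged.
#'
#' @param rec A [waveform_recording()] whose rate is an integer multiple
#'   of 40 Hz.
#' @return A [waveform_recording()] at 40 Hz of length
#'   `floor(n / factor)`.
#' @export
decimate_to_40hz <- function(rec) {
  stopifnot(inherits(rec, "waveform_recording"))
  target <- 40
  factor <- rec$rate / target
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    stop("unsupported rate: ", rec$rate,
         " Hz is not an integer multiple of 40 Hz", call. = FALSE)
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  cutoff <- 0.8 * (target / 2)                 # 16 Hz
  order <- max(8L * factor, 32L)
  if (order %% 2L == 1L) order <- order + 1L   # even order -> odd taps
  h <- signal::fir1(order, cutoff / (rec$rate / 2), type = "low")
  h <- h / sum(h)  # exact unity DC gain: constants pass through unchanged
  lp_flow <- zero_phase_fir(rec$flow, h)
  lp_paw <- zero_phase_fir(rec$paw, h)
  n_out <- floor(length(rec$flow) / factor)
  idx <- (seq_len(n_out) - 1L) * factor + 1L
  waveform_recording(flow = lp_flow[idx], paw = lp_paw[idx], rate = target,
                     start_time = rec$start_time,
                     subject_id = rec$subject_id, mode = rec$mode)
}

# Centred (zero-phase) application of a symmetric FIR; edges are mirror
# padded so constants pass through exactly.
zero_phase_fir <- function(x, h) {
  k <- (length(h) - 1L) / 2L
  n <- length(x)
  if (k >= n) stop("signal shorter than filter", call. = FALSE)
  pad_l <- x[(k + 1L):2L]
  pad_r <- x[(n - 1L):(n - k)]
  xp <- c(pad_l, x, pad_r)
  y <- stats::filter(xp, h, method = "convolution", sides = 2L)
  as.numeric(y[(k + 1L):(k + n)])
}

#' Partition a recording into contiguous analysis segments
#'
#' Tiles the recording with half-open `[start_s, end_s)` segments of the
#' given duration, starting at the recording start. A trailing remainder
#' shorter than one segment is discarded (with a message).
#'
#' @param rec A [waveform_recording()].
#' @param segment_minutes Segment duration in minutes (default 15).
#' @return A data.frame of class `cpvi_segments` with columns `index`,
#'   `start_s`, `end_s`, `label` (`NA`, to be filled from a gold
#'   standard), `mode`.
#' @export
partition_segments <- function(rec, segment_minutes = 15) {
  stopifnot(inherits(rec, "waveform_recording"))
  if (!is.numeric(segment_minutes) || segment_minutes <= 0) {
    stop("segment_minutes must be positive", call. = FALSE)
  }
  seg_s <- segment_minutes * 60
  dur <- duration_s(rec)
  n_seg <- floor(dur / seg_s)
  if (n_seg < 1L) {
    stop("recording (", round(dur / 60, 2), " min) shorter than one ",
         segment_minutes, "-min segment", call. = FALSE)
  }
  rem <- dur - n_seg * seg_s
  if (rem > 1 / rec$rate / 2) {
    message(sprintf("discarding %.2f-min trailing remainder", rem / 60))
  }
  out <- data.frame(
    index = seq_len(n_seg),
    start_s = rec$start_time + (seq_len(n_seg) - 1) * seg_s,
    end_s = rec$start_time + seq_len(n_seg) * seg_s,
    label = NA_integer_,
    mode = rec$mode,
    stringsAsFactors = FALSE)
  class(out) <- c("cpvi_segments", "data.frame")
  out
}
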