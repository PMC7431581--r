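#' Two-channel ventilator waveform recording
#'
#' Container for a simultaneously sampled airway flow / airway pressure
#' recording. Both channels must be the same length, uniformly sampled and
#' free of missing samples: recordings with gaps are rejected at
#' construction rather than silently interpolated.
#'
#' @param flow Numeric vector, airway flow in L/min.
#' @param paw Numeric vector, airway pressure in cmH2O; same length as
#'   `flow`.
#' @param rate Sampling frequency in Hz (> 0).
#' @param start_time Offset of the first sample in seconds (default 0).
#' @param subject_id Opaque subject identifier string.
#' @param mode Ventilation mode, one of `"PSV"`, `"ACV"`, `"UNKNOWN"`.
#'
#' @return An object of class `waveform_recording`: a list with elements
#'   `flow`, `paw`, `rate`, `start_time`, `subject_id`, `mode`.
#' @examples
#' t <- seq(0, 10, by = 1 / 40)
#' rec <- waveform_recording(flow = sin(t), paw = 8 + cos(t), rate = 40)
#' duration_s(rec)
#' @export
waveform_recording <- function(flow, paw, rate, start_time = 0,
                               subject_id = "", mode = "UNKNOWN") {
  if (!is.numeric(flow) || !is.numeric(paw)) {
    stop("flow and paw must be numeric vectors", call. = FALSE)
  }
  if (length(flow) != length(paw)) {
    stop("flow and paw must have equal length", call. = FALSE)
  }
  if (length(flow) == 0L) stop("recording is empty", call. = FALSE)
  if (anyNA(flow) || anyNA(paw) || !all(is.finite(flow)) ||
      !all(is.finite(paw))) {
    stop("recording contains missing or non-finite samples; ",
         "gaps are rejected, not interpolated", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) ||
      rate <= 0) {
    stop("rate must be a single positive number", call. = FALSE)
  }
  mode <- match.arg(mode, c("PSV", "ACV", "UNKNOWN"))
  structure(
    list(flow = as.numeric(flow), paw = as.numeric(paw),
         rate = as.numeric(rate), start_time = as.numeric(start_time),
         subject_id = as.character(subject_id), mode = mode),
    class = "waveform_recording"
  )
}

#' @export
print.waveform_recording <- function(x, ...) {
  cat(sprintf(
    "<waveform_recording> %d samples @ %g Hz (%.1f min), mode %s%s\n",
    length(x$flow), x$rate, duration_s(x) / 60, x$mode,
    if (nzchar(x$subject_id)) paste0(", subject ", x$subject_id) else ""))
  invisible(x)
}

#' Recording duration in seconds
#'
#' @param rec A [waveform_recording()].
#' @return Duration in seconds (`n_samples / rate`).
#' @export
duration_s <- function(rec) {
  stopifnot(inherits(rec, "waveform_recording"))
  length(rec$flow) / rec$rate
}
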