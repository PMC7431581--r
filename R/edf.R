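# Minimal EDF (European Data Format) support: fixed-layout ASCII header,
# 16-bit little-endian samples stored record-by-record, signal-by-signal.
# Only what the package needs: reading two continuous channels selected by
# label substring, and writing such files for fixtures. Not EDF+ (no
# annotations, no discontinuous records).

read_edf_header <- function(con) {
  a <- function(n) {
    raw <- readBin(con, "raw", n = n)
    trimws(rawToChar(raw))
  }
  version <- a(8); patient <- a(80); recording <- a(80)
  startdate <- a(8); starttime <- a(8)
  header_bytes <- as.integer(a(8)); reserved <- a(44)
  n_records <- as.integer(a(8)); record_dur <- as.numeric(a(8))
  ns <- as.integer(a(4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header", call. = FALSE)
  per <- function(n) vapply(seq_len(ns), function(i) a(n), character(1))
  labels <- per(16); transducer <- per(80); phys_dim <- per(8)
  phys_min <- as.numeric(per(8)); phys_max <- as.numeric(per(8))
  dig_min <- as.numeric(per(8)); dig_max <- as.numeric(per(8))
  prefilter <- per(80); spr <- as.integer(per(8)); sig_res <- per(32)
  list(version = version, patient = patient, recording = recording,
       header_bytes = header_bytes, n_records = n_records,
       record_dur = record_dur, ns = ns, labels = labels,
       phys_min = phys_min, phys_max = phys_max, dig_min = dig_min,
       dig_max = dig_max, samples_per_record = spr)
}

read_edf_recording <- function(path, mode = "UNKNOWN", subject_id = "",
                               flow_label = "flow", paw_label = "paw") {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  find <- function(lab) {
    hit <- grep(lab, h$labels, ignore.case = TRUE, fixed = FALSE)
    if (length(hit) == 0L) {
      stop("format error: no EDF signal label matching '", lab, "'",
           call. = FALSE)
    }
    hit[1L]
  }
  i_flow <- find(flow_label); i_paw <- find(paw_label)
  if (h$samples_per_record[i_flow] != h$samples_per_record[i_paw]) {
    stop("flow and paw channels have different sampling rates",
         call. = FALSE)
  }
  total <- sum(h$samples_per_record)
  dig <- readBin(con, "integer", n = total * h$n_records, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(dig) < total * h$n_records) {
    stop("truncated EDF data section", call. = FALSE)
  }
  offs <- c(0L, cumsum(h$samples_per_record))
  chan <- function(i) {
    spr <- h$samples_per_record[i]
    idx <- as.vector(outer(seq_len(spr) + offs[i],
                           (seq_len(h$n_records) - 1L) * total, "+"))
    gain <- (h$phys_max[i] - h$phys_min[i]) / (h$dig_max[i] - h$dig_min[i])
    (dig[idx] - h$dig_min[i]) * gain + h$phys_min[i]
  }
  rate <- h$samples_per_record[i_flow] / h$record_dur
  waveform_recording(flow = chan(i_flow), paw = chan(i_paw), rate = rate,
                     subject_id = subject_id, mode = mode)
}

#' Write a recording as a minimal EDF file
#'
#' Writes the two channels as 16-bit EDF signals (labels `Flow`, `Paw`),
#' one 1-second data record per second of signal; the recording is
#' truncated to a whole number of seconds. Intended for generating test
#' fixtures and for interoperability smoke checks; physical values are
#' quantized to the 16-bit range so the round trip is exact only to the
#' quantization step.
#'
#' @param rec A [waveform_recording()] with an integer sampling rate.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "waveform_recording"))
  spr <- as.integer(round(rec$rate))
  if (abs(spr - rec$rate) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  n_rec <- floor(length(rec$flow) / spr)
  if (n_rec < 1L) stop("recording shorter than one second", call. = FALSE)
  keep <- seq_len(n_rec * spr)
  sig <- list(rec$flow[keep], rec$paw[keep])
  labels <- c("Flow", "Paw"); dims <- c("L/min", "cmH2O")
  pmin_ <- vapply(sig, function(s) floor(min(s)) - 1, numeric(1))
  pmax_ <- vapply(sig, function(s) ceiling(max(s)) + 1, numeric(1))
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, n) {
    s <- formatC(as.character(x), width = -n)
    writeBin(charToRaw(substr(s, 1L, n)), con)
  }
  pad("0", 8); pad(rec$subject_id, 80); pad("cpvi recording", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(256L * 3L, 8); pad("", 44)
  pad(n_rec, 8); pad("1", 8); pad(2L, 4)
  for (x in labels) pad(x, 16)
  for (x in 1:2) pad("", 80)
  for (x in dims) pad(x, 8)
  for (x in pmin_) pad(x, 8)
  for (x in pmax_) pad(x, 8)
  for (x in 1:2) pad(dmin, 8)
  for (x in 1:2) pad(dmax, 8)
  for (x in 1:2) pad("", 80)
  for (x in 1:2) pad(spr, 8)
  for (x in 1:2) pad("", 32)
  dig <- lapply(1:2, function(i) {
    g <- (dmax - dmin) / (pmax_[i] - pmin_[i])
    as.integer(round((sig[[i]] - pmin_[i]) * g + dmin))
  })
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in 1:2) {
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
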