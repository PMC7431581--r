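#' Build a labeled synthetic benchmark corpus
#'
#' Generates `n_recordings` synthetic recordings with known ground truth
#' for benchmarking the detector and the optimization procedure. Roughly
#' `balance` of the recordings contain CP-VI events; modes alternate
#' PSV/ACV. Positive recordings carry one or two 6-min events placed in
#' segments 2 onwards (the detector's baseline is seeded by the first
#' segment, so event-free openings mirror the intended use), drawn from a
#' graded mix of strengths straddling the CP-VI definition: rate shifts
#' of x1.55, x1.8 or x2.2 and asynchrony clusters cycling through all
#' five morphologies at three intensities, from dense-but-gentle mild
#' clusters upward. Every negative recording carries one benign
#' sub-threshold event (a rate x1.2 or x1.24 episode or an 18%
#' asynchrony cluster, rotating — all below the CP-VI definition), so
#' the negative class exercises the detector's threshold rather than
#' being uniformly quiet. Labels always come from the
#' realized breath log, not from the intended design.
#'
#' @param n_recordings Number of recordings (>= 2).
#' @param balance Target fraction of event-carrying recordings
#'   (default 0.5).
#' @param seed Master seed; one recording seed is derived per recording.
#' @param dir Directory to write CSV waveforms plus `manifest.csv`
#'   (`NULL` keeps the corpus in memory only).
#' @param duration_min Minutes per recording (default 60, i.e. four
#'   15-min segments).
#' @param base_rr Baseline respiratory rate (default 18).
#' @param rate Sampling rate in Hz (default 200).
#' @return A list of class `cpvi_corpus`: `recordings` (named list of
#'   [waveform_recording()]), `manifest` (data.frame with `recording_id`,
#'   `segment_index`, `start_s`, `end_s`, `label`, `mode`, and `path` when
#'   written), `windows` (per-recording 3-min truth tables).
#' @export
make_benchmark_corpus <- function(n_recordings = 30, balance = 0.5,
                                  seed = 1L, dir = NULL,
                                  duration_min = 60, base_rr = 18,
                                  rate = 200) {
  if (n_recordings < 2) stop("need at least 2 recordings", call. = FALSE)
  if (duration_min < 30) {
    stop("corpus recordings need >= 30 min: events are placed from the ",
         "second 15-min segment onward", call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  rec_seeds <- sample.int(.Machine$integer.max, n_recordings)
  n_pos <- round(balance * n_recordings)
  is_pos <- rep(FALSE, n_recordings)
  if (n_pos > 0) is_pos[seq_len(n_pos)] <- TRUE
  is_pos <- sample(is_pos)
  rr_mults <- c(1.55, 1.8, 2.2)
  atypes <- c("ineffective_effort", "double_cycling", "premature_cycling",
              "prolonged_cycling", "reverse_triggering")
  # Cluster events come in three intensities. The mild level is a
  # combined episode — a sub-threshold rate rise (x1.32) together with a
  # dense cluster of gentle efforts (fraction 0.4, well above the 30%
  # definition so realized labels are stable, but with the effort
  # amplitude turned far down) — placing its waveform disturbance just
  # above the intended operating threshold; the stronger levels are
  # plain clusters at fractions 0.5 and 0.65 with density-coupled
  # efforts.
  # event slots sit inside segments 2+ with >= 2 min clearance before the
  # next segment boundary, so the smoothed SE response (EMA lag ~2 min)
  # stays within the segment that owns the event
  slot_starts <- c(17, 21, 32, 36, 47, 51)
  slot_starts <- slot_starts[slot_starts + 6 <= duration_min - 1]
  recordings <- list(); manifests <- list(); windows <- list()
  designs <- list()
  pos_i <- 0L; neg_i <- 0L
  for (i in seq_len(n_recordings)) {
    mode <- if (i %% 2 == 1) "PSV" else "ACV"
    events <- list()
    if (is_pos[i]) {
      pos_i <- pos_i + 1L
      n_ev <- 2L
      starts <- sample(slot_starts, n_ev)
      for (j in seq_len(n_ev)) {
        if ((pos_i + j) %% 2 == 0) {
          events <- c(events, list(
            sim_event("rr_change", starts[j], starts[j] + 6,
                      rr_multiplier = rr_mults[1 + (pos_i + j) %% 3])))
        } else {
          ty <- atypes[1 + (pos_i + j) %% 5]
          lev <- 1 + (pos_i + j) %% 3
          events <- c(events, switch(lev,
            list(sim_event("rr_change", starts[j], starts[j] + 6,
                           rr_multiplier = 1.32),
                 sim_event("asynchrony_cluster", starts[j],
                           starts[j] + 6, asynchrony_fraction = 0.4,
                           asynchrony_type = ty, effort_scale = 0.2)),
            list(sim_event("asynchrony_cluster", starts[j],
                           starts[j] + 6, asynchrony_fraction = 0.5,
                           asynchrony_type = ty)),
            list(sim_event("asynchrony_cluster", starts[j],
                           starts[j] + 6, asynchrony_fraction = 0.65,
                           asynchrony_type = ty))))
        }
      }
    } else {
      neg_i <- neg_i + 1L
      s0 <- sample(slot_starts, 1)
      events[[1]] <- switch(1L + neg_i %% 3L,
        sim_event("rr_change", s0, s0 + 6, rr_multiplier = 1.2),
        sim_event("rr_change", s0, s0 + 6, rr_multiplier = 1.24),
        sim_event("asynchrony_cluster", s0, s0 + 6,
                  asynchrony_fraction = 0.18,
                  asynchrony_type = atypes[1 + neg_i %% 5]))
    }
    cfg <- sim_config(mode = mode, base_rr = base_rr,
                      duration_min = duration_min, rate = rate,
                      events = events, seed = rec_seeds[i])
    sim <- simulate_recording(cfg)
    id <- sprintf("rec%03d", i)
    sim$recording$subject_id <- id
    recordings[[id]] <- sim$recording
    windows[[id]] <- sim$windows
    designs[[id]] <- events
    mf <- data.frame(recording_id = id,
                     segment_index = sim$segments$index,
                     start_s = sim$segments$start_s,
                     end_s = sim$segments$end_s,
                     label = sim$segments$label,
                     mode = sim$segments$mode,
                     stringsAsFactors = FALSE)
    manifests[[id]] <- mf
  }
  manifest <- do.call(rbind, manifests)
  rownames(manifest) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(length(recordings))
    for (k in seq_along(recordings)) {
      id <- names(recordings)[k]
      p <- file.path(dir, paste0(id, ".csv"))
      write_recording_csv(recordings[[id]], p)
      paths[k] <- p
    }
    manifest$path <- paths[match(manifest$recording_id,
                                 names(recordings))]
    data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  }
  structure(list(recordings = recordings, manifest = manifest,
                 windows = windows, designs = designs, seed = seed),
            class = "cpvi_corpus")
}

#' Load a benchmark corpus from a manifest
#'
#' Reads a `manifest.csv` written by [make_benchmark_corpus()] (columns
#' `recording_id`, `segment_index`, `label`, `mode`, `path`) and the CSV
#' recordings it points to.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A `cpvi_corpus` object.
#' @export
load_corpus <- function(manifest_path) {
  manifest <- data.table::fread(manifest_path, data.table = FALSE)
  need <- c("recording_id", "segment_index", "label", "mode", "path")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  ids <- unique(manifest$recording_id)
  recordings <- list()
  for (id in ids) {
    p <- manifest$path[match(id, manifest$recording_id)]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    recordings[[id]] <- read_recording(
      p, mode = manifest$mode[match(id, manifest$recording_id)],
      subject_id = id)
  }
  structure(list(recordings = recordings, manifest = manifest,
                 windows = NULL, seed = NA_integer_),
            class = "cpvi_corpus")
}

#' @export
print.cpvi_corpus <- function(x, ...) {
  cat(sprintf("<cpvi_corpus> %d recordings, %d segments (%d positive)\n",
              length(x$recordings), nrow(x$manifest),
              sum(x$manifest$label)))
  invisible(x)
}
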