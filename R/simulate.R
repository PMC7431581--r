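#' Simulation configuration
#'
#' Describes one synthetic two-channel ventilator recording: ventilation
#' mode, baseline respiratory rate, duration, sampling rate, channel noise
#' and a list of [sim_event()]s (respiratory-rate shifts and asynchrony
#' clusters) that define the ground truth.
#'
#' @param mode `"PSV"` or `"ACV"`.
#' @param base_rr Baseline respiratory rate in breaths/min (5-60;
#'   default 18, a typical assisted-ventilation rate).
#' @param duration_min Recording duration in minutes (>= 15 so at least
#'   one detector segment fits).
#' @param rate Sampling rate in Hz (default 200, decimated to 40 Hz by
#'   the analysis pipeline).
#' @param noise_sd Additive Gaussian noise SD as a fraction of each
#'   channel's amplitude (default 0.02).
#' @param events List of [sim_event()]s.
#' @param seed Integer seed making the recording reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(mode = c("PSV", "ACV"), base_rr = 18,
                       duration_min = 15, rate = 200, noise_sd = 0.02,
                       events = list(), seed = 1L) {
  mode <- match.arg(mode)
  if (base_rr < 5 || base_rr > 60) {
    stop("base_rr must be in [5, 60] breaths/min", call. = FALSE)
  }
  if (duration_min < 15) {
    stop("duration_min must be >= 15 (one detector segment)",
         call. = FALSE)
  }
  for (ev in events) {
    stopifnot(inherits(ev, "sim_event"))
    if (ev$end_min > duration_min) {
      stop("config error: event ends at ", ev$end_min,
           " min, beyond the ", duration_min, "-min recording",
           call. = FALSE)
    }
  }
  structure(list(mode = mode, base_rr = base_rr,
                 duration_min = duration_min, rate = rate,
                 noise_sd = noise_sd, events = events,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulation event
#'
#' Either a respiratory-rate shift (`rr_change`; the instantaneous rate is
#' `base_rr * rr_multiplier` while the event is active) or a cluster of
#' asynchronous breaths (`asynchrony_cluster`; each breath inside the
#' event is independently asynchronous with probability
#' `asynchrony_fraction`, drawn as one of the five morphologies).
#'
#' @param kind `"rr_change"` or `"asynchrony_cluster"`.
#' @param start_min,end_min Event span in minutes from recording start.
#' @param rr_multiplier Rate multiplier for `rr_change` (> 0).
#' @param asynchrony_fraction Probability in `[0, 1]` that a breath inside
#'   the cluster is asynchronous.
#' @param asynchrony_type One of `"ineffective_effort"`,
#'   `"double_cycling"`, `"premature_cycling"`, `"prolonged_cycling"`,
#'   `"reverse_triggering"`.
#' @param effort_scale Mean strength of the individual asynchronous
#'   efforts in the cluster, relative to a typical effort. `NA` (default)
#'   couples it to cluster density (`asynchrony_fraction / 0.45`),
#'   reflecting that sicker patients both fight the ventilator more often
#'   and harder; set explicitly to decouple them (e.g. frequent but
#'   gentle efforts).
#' @return An object of class `sim_event`.
#' @export
sim_event <- function(kind = c("rr_change", "asynchrony_cluster"),
                      start_min, end_min, rr_multiplier = 1,
                      asynchrony_fraction = 0,
                      asynchrony_type = c("ineffective_effort",
                                          "double_cycling",
                                          "premature_cycling",
                                          "prolonged_cycling",
                                          "reverse_triggering"),
                      effort_scale = NA_real_) {
  kind <- match.arg(kind)
  asynchrony_type <- match.arg(asynchrony_type)
  if (!is.na(effort_scale) && effort_scale <= 0) {
    stop("effort_scale must be positive", call. = FALSE)
  }
  if (end_min <= start_min) stop("event must have positive duration",
                                 call. = FALSE)
  if (kind == "rr_change" && rr_multiplier <= 0) {
    stop("rr_multiplier must be positive", call. = FALSE)
  }
  if (asynchrony_fraction < 0 || asynchrony_fraction > 1) {
    stop("asynchrony_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, start_min = start_min, end_min = end_min,
                 rr_multiplier = rr_multiplier,
                 asynchrony_fraction = asynchrony_fraction,
                 asynchrony_type = asynchrony_type,
                 effort_scale = effort_scale),
            class = "sim_event")
}

#' Synthesize one breath cycle
#'
#' Single-compartment template breaths. PSV: fast pressure rise to
#' PEEP + support with a decelerating inspiratory flow; ACV
#' (volume-targeted): square inspiratory flow with a ramping pressure.
#' Expiration is passive (exponential) in both modes and is scaled so the
#' flow integral over the full cycle is exactly zero (volume in = volume
#' out). Asynchrony morphologies perturb the template: an ineffective
#' effort adds a mid-expiratory flow deflection toward zero with a small
#' pressure dip and no delivered breath; double cycling stacks a second
#' inspiration after a truncated expiration; premature/prolonged cycling
#' shorten/lengthen the inspiratory time; reverse triggering superimposes
#' an effort-shaped pressure dip late in inspiration.
#'
#' @param mode `"PSV"` or `"ACV"`.
#' @param rate Sampling rate in Hz.
#' @param rr Respiratory rate of this breath in breaths/min.
#' @param ti_frac Inspiratory fraction of the cycle (default 0.33).
#' @param peep PEEP in cmH2O (default 8).
#' @param support Pressure support / driving pressure in cmH2O
#'   (default 10, as on a typical PSV weaning setting).
#' @param peak_flow Peak inspiratory flow in L/min (default 60).
#' @param amp Amplitude scaling factor (breath-to-breath variability).
#' @param asynchrony `NULL` for a normal breath, else one of the five
#'   morphology names.
#' @param effort Strength of the patient-effort deflection relative to the
#'   nominal morphology (default 1). Asynchronous efforts vary widely from
#'   breath to breath; [simulate_recording()] randomizes this.
#' @param phase Where in its nominal span the effort deflection falls, in
#'   `[0, 1]` (default 0.5); randomized per breath by the recording
#'   simulator.
#' @param ti_scale Extra scaling of the inspiratory time applied by the
#'   premature (nominal 0.45) and prolonged (nominal 1.9) cycling
#'   morphologies (default 1).
#' @param gap_s Pause between the stacked inspirations of a double cycle,
#'   in seconds (default 0.25).
#' @param ripple_hz,ripple_phase Frequency (Hz) and phase (rad) of the
#'   respiratory-muscle effort oscillation superimposed on every
#'   asynchronous breath (amplitude scales with `effort`); active patient
#'   effort makes the flow trace visibly erratic, which is the waveform
#'   signature the detector keys on. Randomized per breath by
#'   [simulate_recording()].
#' @return A list with numeric vectors `flow` (L/min) and `paw` (cmH2O)
#'   of equal length (one cycle).
#' @export
simulate_breath <- function(mode = c("PSV", "ACV"), rate = 200, rr = 18,
                            ti_frac = 0.33, peep = 8, support = 10,
                            peak_flow = 60, amp = 1, asynchrony = NULL,
                            effort = 1, phase = 0.5, ti_scale = 1,
                            gap_s = 0.25, ripple_hz = 4,
                            ripple_phase = 0) {
  mode <- match.arg(mode)
  if (rr < 3 || rr > 90 || ti_frac <= 0.05 || ti_frac >= 0.8 ||
      peep < 0 || support <= 0 || peak_flow <= 0 || amp <= 0 ||
      effort <= 0 || phase < 0 || phase > 1 || ti_scale <= 0 ||
      gap_s <= 0) {
    stop("breath parameters out of physiological range", call. = FALSE)
  }
  if (!is.null(asynchrony)) {
    asynchrony <- match.arg(asynchrony,
                            c("ineffective_effort", "double_cycling",
                              "premature_cycling", "prolonged_cycling",
                              "reverse_triggering"))
    if (asynchrony == "premature_cycling") {
      ti_frac <- max(ti_frac * 0.45 * ti_scale, 0.06)
    }
    if (asynchrony == "prolonged_cycling") {
      ti_frac <- min(ti_frac * 1.9 * ti_scale, 0.7)
    }
    if (asynchrony == "double_cycling") {
      # repeated triggering: strong effort oscillation on the stacked pair
      cyc <- double_cycle_breath(mode, rate, rr, ti_frac, peep, support,
                                 peak_flow, amp, gap_s)
      cyc <- add_effort_ripple(cyc, rate, 2 * effort, ripple_hz,
                               ripple_phase)
      return(rebalance_volume(cyc))
    }
    if (asynchrony == "ineffective_effort") {
      # a missed trigger lengthens the apparent cycle
      rr <- max(rr / 1.6, 3)
      ti_frac <- ti_frac / 1.6
    }
  }
  cyc <- base_cycle(mode, rate, rr, ti_frac, peep, support, peak_flow, amp)
  if (!is.null(asynchrony)) {
    t <- (seq_along(cyc$flow) - 1) / rate
    ti <- ti_frac * 60 / rr
    tt <- t[length(t)]
    if (asynchrony == "ineffective_effort") {
      # sharp flow deflection toward zero + pressure dip, no delivered
      # breath; position and size vary with the patient's effort
      tc <- ti + (0.25 + 0.5 * phase) * (tt - ti)
      pulse <- exp(-((t - tc) / 0.10)^2)
      cyc$flow <- cyc$flow + 20 * amp * effort * pulse
      cyc$paw <- cyc$paw - 3 * effort * pulse
    } else if (asynchrony == "reverse_triggering") {
      tc <- (0.6 + 0.35 * phase) * ti
      pulse <- exp(-((t - tc) / 0.08)^2)
      cyc$paw <- cyc$paw - 4 * effort * pulse
      cyc$flow <- cyc$flow +
        10 * amp * effort * exp(-((t - tc - 0.12) / 0.08)^2)
    }
    # prolonged cycling involves the strongest sustained muscular effort
    # (active expiration against the ventilator), hence a larger
    # effort oscillation
    gain <- if (asynchrony == "prolonged_cycling") 3 else 1
    cyc <- add_effort_ripple(cyc, rate, gain * effort, ripple_hz,
                             ripple_phase)
    cyc <- rebalance_volume(cyc)
  }
  cyc
}

# Effort deflections redistribute gas within the cycle but must not
# create net volume; rescale the expiratory lobe so the integral is
# exactly zero again.
rebalance_volume <- function(cyc) {
  neg <- cyc$flow < 0
  s_neg <- sum(cyc$flow[neg])
  if (s_neg < 0) {
    extra <- sum(cyc$flow)
    cyc$flow[neg] <- cyc$flow[neg] * (1 + extra / -s_neg)
  }
  cyc
}

# Irregular respiratory-muscle activity of an actively fighting patient:
# a low-frequency oscillation whose frequency and phase differ breath to
# breath, so consecutive asynchronous breaths never repeat exactly.
add_effort_ripple <- function(cyc, rate, effort, ripple_hz,
                              ripple_phase) {
  t <- (seq_along(cyc$flow) - 1) / rate
  osc <- sin(2 * pi * ripple_hz * t + ripple_phase)
  cyc$flow <- cyc$flow + 2.5 * effort * osc
  cyc$paw <- cyc$paw + 0.5 * effort * osc
  cyc
}

# One clean cycle; expiratory limb scaled so sum(flow) == 0 exactly.
base_cycle <- function(mode, rate, rr, ti_frac, peep, support, peak_flow,
                       amp) {
  t_tot <- 60 / rr
  n <- max(round(rate * t_tot), 8)
  t <- (0:(n - 1)) / rate
  ti <- ti_frac * t_tot
  insp <- t < ti
  flow <- numeric(n); paw <- numeric(n)
  if (mode == "PSV") {
    tau_d <- ti / 2
    flow[insp] <- peak_flow * amp * exp(-t[insp] / tau_d)
    paw[insp] <- peep + support * (1 - exp(-t[insp] / 0.06))
    p_end <- peep + support * (1 - exp(-ti / 0.06))
    paw[!insp] <- peep + (p_end - peep) * exp(-(t[!insp] - ti) / 0.08)
  } else {
    flow[insp] <- 0.75 * peak_flow * amp
    paw[insp] <- peep + 2.5 + (support + 3) * (t[insp] / ti)
    p_end <- peep + 2.5 + support + 3
    paw[!insp] <- peep + (p_end - peep) * exp(-(t[!insp] - ti) / 0.08)
  }
  u <- exp(-(t[!insp] - ti) / 0.4)
  s_u <- sum(u)
  if (s_u > 0) flow[!insp] <- -sum(flow[insp]) / s_u * u
  list(flow = flow, paw = paw)
}

double_cycle_breath <- function(mode, rate, rr, ti_frac, peep, support,
                                peak_flow, amp, gap_s = 0.25) {
  one <- base_cycle(mode, rate, rr, ti_frac, peep, support, peak_flow, amp)
  ti_n <- sum((seq_along(one$flow) - 1) / rate < ti_frac * 60 / rr)
  gap_n <- max(round(gap_s * rate), 1)
  # first inspiration, brief expiration, second full cycle
  idx_insp <- seq_len(ti_n)
  idx_gap <- seq.int(ti_n + 1, min(ti_n + gap_n, length(one$flow)))
  flow <- c(one$flow[idx_insp], one$flow[idx_gap], one$flow)
  paw <- c(one$paw[idx_insp], one$paw[idx_gap], one$paw)
  # rebalance expiration of the trailing cycle so total volume is ~0
  extra <- sum(one$flow[idx_insp]) + sum(one$flow[idx_gap])
  tail_exp <- (length(flow) - (length(one$flow) - ti_n) + 1):length(flow)
  neg <- flow[tail_exp] < 0
  s_neg <- sum(flow[tail_exp][neg])
  if (s_neg < 0) {
    flow[tail_exp][neg] <- flow[tail_exp][neg] * (1 + extra / -s_neg)
  }
  list(flow = flow, paw = paw)
}

#' Simulate a labeled two-channel ventilator recording
#'
#' Concatenates template breaths at the instantaneous respiratory rate
#' (baseline rate times the multiplier of any active rate-shift event,
#' with breath-to-breath timing jitter of 3% CV at baseline, scaled up
#' with the severity of any active event — distressed breathing is
#' irregular in proportion to how hard the patient is fighting the
#' ventilator — and cluster density likewise scales the per-breath effort
#' amplitude, plus 5% amplitude
#' jitter), injects asynchrony morphologies inside cluster events, and
#' adds Gaussian noise. Ground truth follows the CP-VI definition applied
#' to the *realized* breath log: a 3-min window (contiguous tiles) is
#' positive iff the mean realized rate deviates more than 50% from the
#' baseline rate or more than 30% of its breaths are asynchronous; a
#' 15-min segment is positive iff it overlaps a positive window.
#'
#' @param config A [sim_config()].
#' @return A list of class `cpvi_simulation`: `recording`
#'   ([waveform_recording()]), `breaths` (per-breath log), `windows`
#'   (3-min truth table), `segments` (15-min labels, a `cpvi_segments`
#'   data.frame with `label` filled).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(config$seed)
  rate <- config$rate
  dur_s <- config$duration_min * 60
  flow <- vector("list", 4096); paw <- vector("list", 4096)
  t_start <- dur_breath <- rr_inst <- numeric(0)
  async <- character(0)
  tcur <- 0; b <- 0L
  while (tcur < dur_s) {
    mult <- 1; af <- 0; atype <- NA_character_; es <- NA_real_
    for (ev in config$events) {
      if (tcur >= ev$start_min * 60 && tcur < ev$end_min * 60) {
        if (ev$kind == "rr_change") mult <- ev$rr_multiplier
        else {
          af <- ev$asynchrony_fraction
          atype <- ev$asynchrony_type
          es <- ev$effort_scale
        }
      }
    }
    # distress severity: rate shifts and asynchrony clusters disturb
    # breath timing, and denser clusters come with stronger efforts
    severity <- max(2 * abs(mult - 1), af / 0.45)
    jitter_cv <- 0.03 * (1 + severity)
    rr_b <- config$base_rr * mult * (1 + rnorm(1, 0, jitter_cv))
    rr_b <- min(max(rr_b, 4), 80)
    amp_b <- max(1 + rnorm(1, 0, 0.05), 0.3)
    is_async <- af > 0 && runif(1) < af
    br <- if (is_async) {
      simulate_breath(config$mode, rate = rate, rr = rr_b, amp = amp_b,
                      asynchrony = atype,
                      effort = runif(1, 0.75, 1.3) *
                        (if (is.na(es)) af / 0.45 else es),
                      phase = runif(1),
                      ti_scale = runif(1, 0.75, 1.25),
                      gap_s = runif(1, 0.12, 0.4),
                      ripple_hz = runif(1, 3.5, 6),
                      ripple_phase = runif(1, 0, 2 * pi))
    } else {
      simulate_breath(config$mode, rate = rate, rr = rr_b, amp = amp_b)
    }
    b <- b + 1L
    if (b > length(flow)) {
      length(flow) <- 2L * length(flow); length(paw) <- length(flow)
    }
    flow[[b]] <- br$flow; paw[[b]] <- br$paw
    nb <- length(br$flow)
    t_start <- c(t_start, tcur)
    dur_breath <- c(dur_breath, nb / rate)
    rr_inst <- c(rr_inst, 60 / (nb / rate))
    async <- c(async, if (is_async) atype else NA_character_)
    tcur <- tcur + nb / rate
  }
  flow <- unlist(flow[seq_len(b)]); paw <- unlist(paw[seq_len(b)])
  n_keep <- dur_s * rate
  flow <- flow[seq_len(n_keep)]; paw <- paw[seq_len(n_keep)]
  if (config$noise_sd > 0) {
    flow <- flow + rnorm(n_keep, 0, config$noise_sd * diff(range(flow)))
    paw <- paw + rnorm(n_keep, 0, config$noise_sd * diff(range(paw)))
  }
  rec <- waveform_recording(flow, paw, rate, mode = config$mode)
  breaths <- data.frame(t_start = t_start, duration_s = dur_breath,
                        rr_inst = rr_inst, asynchrony = async,
                        stringsAsFactors = FALSE)
  truth <- label_ground_truth(breaths, config)
  structure(list(recording = rec, breaths = breaths,
                 windows = truth$windows, segments = truth$segments,
                 config = config),
            class = "cpvi_simulation")
}

# Pure labeling function: realized breath log -> 3-min window truth and
# 15-min segment labels (relabeling the same log is bit-identical).
label_ground_truth <- function(breaths, config) {
  n_w <- floor(config$duration_min / 3)
  w0 <- (seq_len(n_w) - 1) * 180
  rows <- lapply(seq_len(n_w), function(w) {
    inw <- breaths$t_start >= w0[w] & breaths$t_start < w0[w] + 180
    rrm <- mean(breaths$rr_inst[inw])
    af <- mean(!is.na(breaths$asynchrony[inw]))
    rr_chg <- abs(rrm - config$base_rr) / config$base_rr
    data.frame(window = w, start_s = w0[w], end_s = w0[w] + 180,
               mean_rr = rrm, rr_change = rr_chg, async_frac = af,
               positive = (rr_chg > 0.5) | (af > 0.3))
  })
  windows <- do.call(rbind, rows)
  n_seg <- floor(config$duration_min / 15)
  segs <- lapply(seq_len(n_seg), function(s) {
    s0 <- (s - 1) * 900; s1 <- s * 900
    ov <- windows$start_s < s1 & windows$end_s > s0
    data.frame(index = s, start_s = s0, end_s = s1,
               label = as.integer(any(windows$positive[ov])),
               mode = config$mode, stringsAsFactors = FALSE)
  })
  segments <- do.call(rbind, segs)
  class(segments) <- c("cpvi_segments", "data.frame")
  list(windows = windows, segments = segments)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}
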