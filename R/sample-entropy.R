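#' Sample Entropy settings
#'
#' Bundles the tunable settings of the sliding-window Sample Entropy
#' analysis: embedding dimension `m`, tolerance expressed as a multiple of
#' each window's standard deviation, window length and overlap, and the
#' exponential-moving-average smoothing span.
#'
#' @param m Embedding dimension (positive integer).
#' @param r_factor Tolerance as a multiple of the window SD (> 0).
#' @param window_s Window length in seconds (default 30).
#' @param overlap_frac Window overlap fraction in `[0, 1)` (default 0.5,
#'   i.e. a 15-s stride for 30-s windows).
#' @param ema_span Smoothing span in windows (default 8).
#' @param smoothing_on Apply the EMA to the raw series (default `TRUE`).
#' @return An object of class `se_params`.
#' @export
se_params <- function(m = 2L, r_factor = 0.2, window_s = 30,
                      overlap_frac = 0.5, ema_span = 8L,
                      smoothing_on = TRUE) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop("m must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(r_factor) || r_factor <= 0) {
    stop("r_factor must be positive", call. = FALSE)
  }
  if (!is.numeric(window_s) || window_s <= 0) {
    stop("window_s must be positive", call. = FALSE)
  }
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop("overlap_frac must be in [0, 1)", call. = FALSE)
  }
  if (ema_span < 1 || ema_span != round(ema_span)) {
    stop("ema_span must be a positive integer", call. = FALSE)
  }
  structure(list(m = as.integer(m), r_factor = r_factor,
                 window_s = window_s, overlap_frac = overlap_frac,
                 ema_span = as.integer(ema_span),
                 smoothing_on = isTRUE(smoothing_on)),
            class = "se_params")
}

#' Chebyshev distance between two vectors
#'
#' The maximum absolute componentwise difference, the distance under which
#' Sample Entropy template matches are counted.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A single nonnegative number.
#' @examples
#' chebyshev_distance(c(0, 0), c(3, -4)) # 4
#' @export
chebyshev_distance <- function(u, v) {
  if (length(u) != length(v)) {
    stop("u and v must have equal length", call. = FALSE)
  }
  max(abs(u - v))
}

#' Sample Entropy of a series
#'
#' `-ln(A / B)` where `B` counts pairs of `m`-sample templates within
#' Chebyshev distance `r_abs` of each other (self-matches excluded, start
#' indices `1..N-m`) and `A` counts the pairs that still match when
#' extended to `m + 1` samples. Returned in nats. When no template pairs
#' match at length `m` or at length `m + 1` the statistic is undefined and
#' `NA` is returned rather than a capped value.
#'
#' @param x Numeric series of length `N > m + 2`, all finite.
#' @param m Embedding dimension (positive integer).
#' @param r_abs Absolute tolerance (> 0), typically a multiple of `sd(x)`.
#' @return A nonnegative number, or `NA` when undefined.
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(500), m = 2, r_abs = 0.2)
#' sample_entropy(rep(1, 100), m = 2, r_abs = 0.1) # 0: perfectly regular
#' @export
sample_entropy <- function(x, m, r_abs) {
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x))) {
    stop("x must be a finite numeric vector", call. = FALSE)
  }
  if (m < 1 || m != round(m)) {
    stop("m must be a positive integer", call. = FALSE)
  }
  if (length(x) <= m + 2) {
    stop("series length must exceed m + 2", call. = FALSE)
  }
  if (!is.numeric(r_abs) || r_abs <= 0) {
    stop("r_abs must be positive", call. = FALSE)
  }
  cnt <- .sampen_counts(as.numeric(x), as.integer(m), as.numeric(r_abs))
  b <- cnt[1L, m]; a <- cnt[2L, m]
  if (b == 0 || a == 0) return(NA_real_)
  -log(a / b)
}

#' Sliding-window Sample Entropy series
#'
#' Slides a window of `params$window_s` seconds across one channel (windows
#' start at the first sample and step by `window_s * (1 - overlap_frac)`;
#' only complete windows are evaluated), computes Sample Entropy per window
#' with tolerance `r_factor * SD(window)`, and optionally smooths the series
#' with an [ema_smooth()] of span `params$ema_span`. Windows with zero SD
#' yield `NA`.
#'
#' @param x Numeric channel samples (typically 40 Hz after
#'   [decimate_to_40hz()]), or a [waveform_recording()] combined with
#'   `channel`.
#' @param params An [se_params()] object.
#' @param rate Sampling rate in Hz (ignored when `x` is a recording).
#' @param channel `"flow"` or `"paw"` when `x` is a recording.
#' @return An object of class `se_series`: a data.frame with columns
#'   `time_s` (window centres), `se_raw`, `se` (smoothed if requested),
#'   `defined`; attributes `params`, `channel`, `smoothed`.
#' @export
se_sliding_series <- function(x, params = se_params(), rate = 40,
                              channel = c("flow", "paw")) {
  channel <- match.arg(channel)
  t0 <- 0
  if (inherits(x, "waveform_recording")) {
    rate <- x$rate
    t0 <- x$start_time
    x <- x[[channel]]
  }
  stopifnot(inherits(params, "se_params"))
  win <- params$window_s * rate
  if (abs(win - round(win)) > 1e-9) {
    stop("window_s * rate must be an integer number of samples",
         call. = FALSE)
  }
  win <- as.integer(round(win))
  if (win <= params$m + 2) {
    stop("window holds too few samples for m = ", params$m, call. = FALSE)
  }
  if (length(x) < win) {
    stop("signal shorter than one window", call. = FALSE)
  }
  stride <- win * (1 - params$overlap_frac)
  if (abs(stride - round(stride)) > 1e-9) {
    stop("window stride must be an integer number of samples",
         call. = FALSE)
  }
  stride <- as.integer(round(stride))
  starts <- seq.int(1L, length(x) - win + 1L, by = stride)
  vals <- .se_sliding_kernel(as.numeric(x), as.integer(starts), win,
                             params$m, params$r_factor)
  raw <- as.numeric(vals[params$m, 1L, ])
  times <- t0 + (starts - 1) / rate + params$window_s / 2
  out <- data.frame(time_s = times, se_raw = raw, se = raw,
                    defined = !is.na(raw))
  class(out) <- c("se_series", "data.frame")
  attr(out, "params") <- params
  attr(out, "channel") <- channel
  attr(out, "smoothed") <- FALSE
  if (params$smoothing_on) out <- ema_smooth(out, params$ema_span)
  out
}

#' Exponential moving average smoothing
#'
#' Recursive filter `y_t = alpha * x_t + (1 - alpha) * y_{t-1}` with
#' `alpha = 2 / (span + 1)`, initialized at the first defined value.
#' Undefined (`NA`) inputs carry the previous smoothed state forward and
#' stay `NA` in the output.
#'
#' @param series An `se_series` (smooths the `se_raw` column into `se`) or
#'   a plain numeric vector.
#' @param span Smoothing span in periods; `span = 1` is the identity.
#' @return Same shape as the input.
#' @export
ema_smooth <- function(series, span = 8L) {
  if (span < 1 || span != round(span)) {
    stop("span must be a positive integer", call. = FALSE)
  }
  smooth_vec <- function(x) {
    if (length(x) == 0L) stop("empty series", call. = FALSE)
    alpha <- 2 / (span + 1)
    y <- rep(NA_real_, length(x))
    state <- NA_real_
    for (i in seq_along(x)) {
      if (is.na(x[i])) next
      state <- if (is.na(state)) x[i] else alpha * x[i] + (1 - alpha) * state
      y[i] <- state
    }
    y
  }
  if (inherits(series, "se_series")) {
    series$se <- smooth_vec(series$se_raw)
    attr(series, "smoothed") <- TRUE
    series
  } else {
    smooth_vec(as.numeric(series))
  }
}

#' Sliding-window Sample Entropy for a grid of settings
#'
#' Computes the whole `(m, r_factor)` grid in one pass over the signal:
#' the template-counting kernel yields every embedding dimension up to
#' `max(m_values)` per tolerance at no extra cost, which is what makes the
#' repeated-holdout optimization tractable.
#'
#' @inheritParams se_sliding_series
#' @param m_values Integer vector of embedding dimensions.
#' @param r_values Numeric vector of tolerance factors (multiples of the
#'   window SD).
#' @param window_s,overlap_frac,ema_span,smoothing_on As in [se_params()].
#' @return A list with `times` (window centres) and `se`, an array of
#'   dimension `(length(m_values), length(r_values), n_windows)` of
#'   smoothed SE values (`NA` where undefined), plus `se_raw`.
#' @export
se_sliding_grid <- function(x, m_values = 1:20,
                            r_values = c(0.1, 0.2, 0.3, 0.4), rate = 40,
                            channel = c("flow", "paw"), window_s = 30,
                            overlap_frac = 0.5, ema_span = 8L,
                            smoothing_on = TRUE) {
  channel <- match.arg(channel)
  t0 <- 0
  if (inherits(x, "waveform_recording")) {
    rate <- x$rate
    t0 <- x$start_time
    x <- x[[channel]]
  }
  m_values <- as.integer(m_values)
  stopifnot(all(m_values >= 1L), all(r_values > 0))
  win <- as.integer(round(window_s * rate))
  stride <- as.integer(round(win * (1 - overlap_frac)))
  if (length(x) < win) stop("signal shorter than one window", call. = FALSE)
  starts <- seq.int(1L, length(x) - win + 1L, by = stride)
  max_m <- max(m_values)
  vals <- .se_sliding_kernel(as.numeric(x), as.integer(starts), win,
                             max_m, as.numeric(r_values))
  raw <- vals[m_values, , , drop = FALSE]
  dimnames(raw) <- list(m = m_values, r = r_values, NULL)
  se <- raw
  if (smoothing_on) {
    for (i in seq_along(m_values)) {
      for (j in seq_along(r_values)) {
        se[i, j, ] <- ema_smooth(raw[i, j, ], ema_span)
      }
    }
  }
  list(times = t0 + (starts - 1) / rate + window_s / 2,
       se = se, se_raw = raw, m_values = m_values, r_values = r_values)
}
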