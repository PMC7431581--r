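#' Per-segment Sample Entropy features
#'
#' Aggregates an SE series into one feature per analysis segment: the mean
#' or the maximum of the defined SE points whose window centres fall in
#' the segment's half-open interval `[start_s, end_s)` (a window straddling
#' a boundary belongs to the segment containing its centre). A segment with
#' fewer than `min_defined` defined points is marked unevaluable
#' (`value = NA`).
#'
#' @param series An `se_series` from [se_sliding_series()].
#' @param segments A `cpvi_segments` data.frame from [partition_segments()].
#' @param kind `"max"` (default, the better-performing feature) or
#'   `"mean"`.
#' @param min_defined Minimum defined SE points per segment (default 10).
#' @return A data.frame of class `segment_features`: `segment_index`,
#'   `kind`, `channel`, `value`, `n_defined`, `evaluable`.
#' @export
segment_features <- function(series, segments, kind = c("max", "mean"),
                             min_defined = 10L) {
  kind <- match.arg(kind)
  stopifnot(inherits(series, "se_series"), is.data.frame(segments))
  agg <- if (kind == "max") max else mean
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    inb <- series$time_s >= segments$start_s[i] &
      series$time_s < segments$end_s[i]
    v <- series$se[inb]
    v <- v[!is.na(v)]
    n_def <- length(v)
    data.frame(segment_index = segments$index[i], kind = kind,
               channel = attr(series, "channel") %||% NA_character_,
               value = if (n_def >= min_defined) agg(v) else NA_real_,
               n_defined = n_def,
               evaluable = n_def >= min_defined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("segment_features", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evolving personal SE baseline
#'
#' The baseline is initialized with the first evaluable segment's feature
#' value and thereafter only ever decreases: it is the running minimum of
#' the features seen so far, so a quiet (low-entropy) spell permanently
#' tightens the reference each later segment is compared against.
#'
#' @param baseline Current baseline value (nats).
#' @param initialized Has a first segment been consumed yet?
#' @return An object of class `baseline_state`.
#' @export
baseline_state <- function(baseline = NA_real_, initialized = FALSE) {
  structure(list(baseline = baseline, initialized = isTRUE(initialized)),
            class = "baseline_state")
}

#' Update the baseline with a new segment feature
#'
#' First evaluable feature sets the baseline; afterwards
#' `baseline <- min(baseline, value)`. An unevaluable feature (`NA`)
#' leaves the state unchanged.
#'
#' @param state A [baseline_state()].
#' @param value The segment's feature value (nats), or `NA`.
#' @return The updated [baseline_state()].
#' @export
update_baseline <- function(state, value) {
  stopifnot(inherits(state, "baseline_state"))
  if (is.na(value)) return(state)
  if (!state$initialized) return(baseline_state(value, TRUE))
  baseline_state(min(state$baseline, value), TRUE)
}

#' Percent change from the personal baseline
#'
#' `PC = 100 * (value - baseline) / baseline`. Requires an initialized,
#' strictly positive baseline.
#'
#' @param value Segment feature value (nats).
#' @param state A [baseline_state()].
#' @return Percent change (may be negative).
#' @export
percent_change <- function(value, state) {
  stopifnot(inherits(state, "baseline_state"))
  if (!state$initialized) stop("baseline not initialized", call. = FALSE)
  if (!is.finite(state$baseline) || state$baseline <= 0) {
    stop("undefined percent change: baseline is not positive",
         call. = FALSE)
  }
  100 * (value - state$baseline) / state$baseline
}

#' Flag CP-VI segments from a feature sequence
#'
#' Walks the segments in order. For each evaluable segment the percent
#' change (PC) of its SE feature from the evolving personal baseline is
#' computed and the segment is flagged as containing a complex
#' patient-ventilator interaction when `PC > th` (strict: a tie at exactly
#' `th` is negative). The baseline is updated *after* the segment is
#' evaluated, so detection is causal: a low-entropy segment lowers the
#' reference for later segments but cannot re-label itself. The first
#' evaluable segment defines the baseline (PC = 0) and therefore can never
#' be flagged; `baseline_init_k > 1` instead seeds the baseline with the
#' minimum feature over the first `k` evaluable segments, guarding against
#' a CP-VI-containing first period inflating the reference.
#'
#' @param features A `segment_features` data.frame (one channel, one
#'   kind), ordered by `segment_index`, or a bare numeric vector of
#'   feature values.
#' @param th Detection threshold on PC, in percent.
#' @param baseline_init_k Number of leading evaluable segments whose
#'   minimum seeds the baseline (default 1, the first segment alone).
#' @return A data.frame of class `cpvi_detections`: `segment_index`,
#'   `feature`, `baseline_used`, `pc`, `cpvi` (`NA` for unevaluable
#'   segments), `th`.
#' @export
detect_cpvi <- function(features, th, baseline_init_k = 1L) {
  if (is.numeric(features)) {
    features <- data.frame(segment_index = seq_along(features),
                           value = as.numeric(features))
  }
  stopifnot(is.data.frame(features), "value" %in% names(features))
  if (nrow(features) == 0L) stop("empty feature list", call. = FALSE)
  if (!is.numeric(th) || length(th) != 1L) {
    stop("th must be a single percent value", call. = FALSE)
  }
  if (is.unsorted(features$segment_index)) {
    stop("features must be ordered by segment_index", call. = FALSE)
  }
  v <- features$value
  n <- length(v)
  state <- baseline_state()
  if (baseline_init_k > 1L) {
    lead <- v[!is.na(v)]
    lead <- head(lead, baseline_init_k)
    if (length(lead) > 0L) state <- baseline_state(min(lead), TRUE)
  }
  baseline_used <- pc <- rep(NA_real_, n)
  flag <- rep(NA, n)
  for (i in seq_len(n)) {
    if (is.na(v[i])) next
    if (!state$initialized) state <- baseline_state(v[i], TRUE)
    baseline_used[i] <- state$baseline
    pc[i] <- percent_change(v[i], state)
    flag[i] <- pc[i] > th
    state <- update_baseline(state, v[i])
  }
  out <- data.frame(segment_index = features$segment_index,
                    feature = v, baseline_used = baseline_used, pc = pc,
                    cpvi = flag, th = th, stringsAsFactors = FALSE)
  class(out) <- c("cpvi_detections", "data.frame")
  out
}

# Vectorized percent-change sequence used by the grid search; must agree
# with detect_cpvi (tested). Returns PC per segment for one ordered
# feature vector, NA where unevaluable.
pc_sequence <- function(v, baseline_init_k = 1L) {
  n <- length(v)
  pc <- rep(NA_real_, n)
  ok <- which(!is.na(v))
  if (length(ok) == 0L) return(pc)
  vv <- v[ok]
  base <- c(vv[1L], cummin(vv)[-length(vv)])
  if (baseline_init_k > 1L) {
    seed <- min(head(vv, baseline_init_k))
    base <- pmin(base, seed)
  }
  pc[ok] <- 100 * (vv - base) / base
  pc
}
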