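#' Grid specification for the repeated-holdout optimization
#'
#' The search space over Sample Entropy settings and detection thresholds,
#' together with the repeated-holdout design: embedding dimensions
#' 1..20, tolerance factors 0.1-0.4, thresholds 15-50% in 5% steps, both
#' derived features and both channels, 15 repetitions of a random 70/30
#' optimization/validation split.
#'
#' @param m_values Integer embedding dimensions (default `1:20`).
#' @param r_values Tolerance factors (default `c(0.1, 0.2, 0.3, 0.4)`).
#' @param th_values Thresholds in percent (default `seq(15, 50, by = 5)`).
#' @param features Feature kinds, subset of `c("max", "mean")`.
#' @param channels Channels, subset of `c("flow", "paw")`.
#' @param n_repeats Holdout repetitions (default 15).
#' @param opt_fraction Fraction assigned to the optimization subset
#'   (default 0.70; sizes are `round(fraction * n)` and the remainder).
#' @param seed Master seed; one split seed is derived per repetition.
#' @param window_s,overlap_frac,ema_span SE series settings, as in
#'   [se_params()].
#' @param min_defined Minimum defined SE points per evaluable segment.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(m_values = 1:20, r_values = c(0.1, 0.2, 0.3, 0.4),
                      th_values = seq(15, 50, by = 5),
                      features = c("max", "mean"),
                      channels = c("flow", "paw"), n_repeats = 15L,
                      opt_fraction = 0.70, seed = 1L, window_s = 30,
                      overlap_frac = 0.5, ema_span = 8L,
                      min_defined = 10L) {
  features <- match.arg(features, c("max", "mean"), several.ok = TRUE)
  channels <- match.arg(channels, c("flow", "paw"), several.ok = TRUE)
  if (length(m_values) == 0 || length(r_values) == 0 ||
      length(th_values) == 0) {
    stop("all grids must be non-empty", call. = FALSE)
  }
  if (opt_fraction <= 0 || opt_fraction >= 1) {
    stop("opt_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(m_values = as.integer(m_values),
                 r_values = as.numeric(r_values),
                 th_values = as.numeric(th_values), features = features,
                 channels = channels, n_repeats = as.integer(n_repeats),
                 opt_fraction = opt_fraction, seed = as.integer(seed),
                 window_s = window_s, overlap_frac = overlap_frac,
                 ema_span = as.integer(ema_span),
                 min_defined = as.integer(min_defined)),
            class = "grid_spec")
}

#' Random holdout split of labeled segments
#'
#' Splits `n` segments into disjoint, exhaustive optimization and
#' validation subsets with `round(fraction * n)` segments on the
#' optimization side (92 segments at 0.70 give the 64/28 split).
#' Reproducible under a fixed seed. `stratify` balances the class ratio
#' across the two subsets; the default is a simple random split.
#'
#' @param labels Binary gold-standard label per segment (both classes must
#'   be present).
#' @param fraction Optimization-side fraction (default 0.70).
#' @param seed Integer seed.
#' @param stratify Class-stratified split (default `FALSE`).
#' @return A list with integer index vectors `opt` and `val`.
#' @export
holdout_split <- function(labels, fraction = 0.70, seed = 1L,
                          stratify = FALSE) {
  n <- length(labels)
  if (n < 4L) stop("need at least 4 labeled segments", call. = FALSE)
  if (length(unique(labels[!is.na(labels)])) < 2L) {
    stop("split error: only one class present", call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  if (stratify) {
    opt <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      opt <- c(opt, sample(idx, round(fraction * length(idx))))
    }
    opt <- sort(opt)
  } else {
    opt <- sort(sample.int(n, round(fraction * n)))
  }
  list(opt = opt, val = setdiff(seq_len(n), opt))
}

#' Precompute Sample Entropy features for a whole corpus and grid
#'
#' Decimates every recording to 40 Hz, computes the sliding-window SE
#' series for every `(channel, m, r)` setting in one kernel pass per
#' tolerance, smooths each series, and aggregates the per-segment
#' mean/max features. Entropy is computed once here; the repeated-holdout
#' grid search then only re-scores cheap detections.
#'
#' @param corpus A `cpvi_corpus` from [make_benchmark_corpus()] or
#'   [load_corpus()].
#' @param grid A [grid_spec()].
#' @param segment_minutes Segment duration in minutes (default 15).
#' @return An object of class `se_cache`: list with `features` (array
#'   `[segment, channel, kind, m, r]`), `manifest` (row-aligned with the
#'   segment dimension), `grid`.
#' @export
build_se_cache <- function(corpus, grid = grid_spec(),
                           segment_minutes = 15) {
  stopifnot(inherits(corpus, "cpvi_corpus"), inherits(grid, "grid_spec"))
  manifest <- corpus$manifest
  ord <- order(manifest$recording_id, manifest$segment_index)
  manifest <- manifest[ord, , drop = FALSE]
  n_seg <- nrow(manifest)
  nm <- length(grid$m_values); nr <- length(grid$r_values)
  feats <- array(NA_real_,
                 dim = c(n_seg, length(grid$channels),
                         length(grid$features), nm, nr),
                 dimnames = list(NULL, grid$channels, grid$features,
                                 grid$m_values, grid$r_values))
  n_def <- array(0L, dim = c(n_seg, length(grid$channels)))
  for (id in unique(manifest$recording_id)) {
    rec <- corpus$recordings[[id]]
    if (is.null(rec)) stop("recording ", id, " missing from corpus",
                           call. = FALSE)
    if (rec$rate != 40) rec <- decimate_to_40hz(rec)
    rows <- which(manifest$recording_id == id)
    segs <- manifest[rows, , drop = FALSE]
    for (ci in seq_along(grid$channels)) {
      ch <- grid$channels[ci]
      g <- se_sliding_grid(rec, m_values = grid$m_values,
                           r_values = grid$r_values, channel = ch,
                           window_s = grid$window_s,
                           overlap_frac = grid$overlap_frac,
                           ema_span = grid$ema_span)
      for (si in seq_along(rows)) {
        inb <- g$times >= segs$start_s[si] & g$times < segs$end_s[si]
        sub <- g$se[, , inb, drop = FALSE]      # [m, r, win]
        def_counts <- apply(!is.na(sub), c(1, 2), sum)
        n_def[rows[si], ci] <- max(def_counts)
        for (ki in seq_along(grid$features)) {
          agg <- if (grid$features[ki] == "max") {
            suppressWarnings(apply(sub, c(1, 2), max, na.rm = TRUE))
          } else {
            apply(sub, c(1, 2), mean, na.rm = TRUE)
          }
          agg[!is.finite(agg)] <- NA_real_
          agg[def_counts < grid$min_defined] <- NA_real_
          feats[rows[si], ci, ki, , ] <- agg
        }
      }
    }
  }
  structure(list(features = feats, manifest = manifest, grid = grid),
            class = "se_cache")
}

#' Repeated-holdout grid search maximizing mean MCC
#'
#' For every combination of `(channel, feature, m, r)` the percent-change
#' sequence is computed once per recording (the baseline evolves within a
#' recording); every threshold then yields a binary detection per segment.
#' Each of the `n_repeats` random 70/30 splits scores every combination by
#' its MCC on the optimization subset; combinations are summarized by
#' their mean MCC across repetitions. All features and channels are
#' evaluated on identical splits for comparability.
#'
#' @param cache An `se_cache` from [build_se_cache()].
#' @param grid A [grid_spec()]; defaults to the one stored in the cache.
#' @return An object of class `cpvi_grid_result`: `combos` (data.frame
#'   `channel`, `feature`, `m`, `r`, `th`, `mean_mcc`, `n_missing`),
#'   `rep_mcc` (matrix combos x repetitions), `pc` (percent-change matrix
#'   segments x (channel,feature,m,r)), `splits`, `manifest`, `grid`.
#' @export
grid_search <- function(cache, grid = NULL) {
  stopifnot(inherits(cache, "se_cache"))
  if (is.null(grid)) grid <- cache$grid
  manifest <- cache$manifest
  labels <- manifest$label
  n_seg <- nrow(manifest)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(grid$seed)
  rep_seeds <- sample.int(.Machine$integer.max, grid$n_repeats)
  splits <- lapply(rep_seeds, function(s)
    holdout_split(labels, grid$opt_fraction, seed = s))
  rec_rows <- split(seq_len(n_seg), manifest$recording_id)
  combo4 <- expand.grid(m = grid$m_values, r = grid$r_values,
                        feature = grid$features, channel = grid$channels,
                        stringsAsFactors = FALSE)
  n_c4 <- nrow(combo4)
  pc <- matrix(NA_real_, n_seg, n_c4)
  for (k in seq_len(n_c4)) {
    mi <- match(combo4$m[k], grid$m_values)
    ri <- match(combo4$r[k], grid$r_values)
    ki <- match(combo4$feature[k], grid$features)
    ci <- match(combo4$channel[k], grid$channels)
    v <- cache$features[, ci, ki, mi, ri]
    for (rows in rec_rows) pc[rows, k] <- pc_sequence(v[rows])
  }
  combos <- merge(combo4, data.frame(th = grid$th_values))
  combos <- combos[order(combos$channel, combos$feature, combos$m,
                         combos$r, combos$th), , drop = FALSE]
  rownames(combos) <- NULL
  rep_mcc <- matrix(NA_real_, nrow(combos), grid$n_repeats)
  combos$n_missing <- 0L
  for (j in seq_len(nrow(combos))) {
    k <- which(combo4$m == combos$m[j] & combo4$r == combos$r[j] &
               combo4$feature == combos$feature[j] &
               combo4$channel == combos$channel[j])
    pred <- pc[, k] > combos$th[j]
    combos$n_missing[j] <- sum(is.na(pred))
    for (rp in seq_len(grid$n_repeats)) {
      idx <- splits[[rp]]$opt
      keep <- idx[!is.na(pred[idx]) & !is.na(labels[idx])]
      if (length(keep) == 0L) next
      rep_mcc[j, rp] <- mcc(confusion(pred[keep], labels[keep]))
    }
  }
  combos$mean_mcc <- rowMeans(rep_mcc)
  structure(list(combos = combos, rep_mcc = rep_mcc, pc = pc,
                 combo4 = combo4, splits = splits, manifest = manifest,
                 grid = grid),
            class = "cpvi_grid_result")
}

#' @export
print.cpvi_grid_result <- function(x, ...) {
  cat(sprintf(
    "<cpvi_grid_result> %d combinations x %d repetitions on %d segments\n",
    nrow(x$combos), ncol(x$rep_mcc), nrow(x$manifest)))
  best <- select_optimal(x)
  cat(sprintf("  best: channel %s, feature %s, m=%d, r=%g, Th=%g%% ",
              best$channel, best$feature, best$m, best$r, best$th))
  cat(sprintf("(mean MCC %.3f)\n", best$mean_mcc))
  invisible(x)
}

#' Select the optimal combination from a grid result
#'
#' The argmax of mean MCC across repetitions. Ties are broken by
#' parsimony: smallest `m`, then smallest `r`, then smallest `Th` (then
#' flow before paw and max before mean, for full determinism). Also
#' reports in how many repetitions the winner attained that repetition's
#' maximum MCC.
#'
#' @param result A `cpvi_grid_result`.
#' @return A list of class `cpvi_optimum`: `channel`, `feature`, `m`,
#'   `r`, `th`, `mean_mcc`, `n_top_reps`, `row`.
#' @export
select_optimal <- function(result) {
  stopifnot(inherits(result, "cpvi_grid_result"))
  cb <- result$combos
  if (all(is.na(cb$mean_mcc))) {
    stop("selection error: no combination has a defined mean MCC",
         call. = FALSE)
  }
  ord <- order(-cb$mean_mcc, cb$m, cb$r, cb$th,
               match(cb$channel, c("flow", "paw")),
               match(cb$feature, c("max", "mean")))
  j <- ord[1L]
  rep_max <- apply(result$rep_mcc, 2, max, na.rm = TRUE)
  n_top <- sum(result$rep_mcc[j, ] >= rep_max - 1e-12, na.rm = TRUE)
  structure(list(channel = cb$channel[j], feature = cb$feature[j],
                 m = cb$m[j], r = cb$r[j], th = cb$th[j],
                 mean_mcc = cb$mean_mcc[j], n_top_reps = n_top, row = j),
            class = "cpvi_optimum")
}

#' @export
print.cpvi_optimum <- function(x, ...) {
  cat(sprintf(
    "<cpvi_optimum> channel %s, feature %s, m=%d, r=%g, Th=%g%%\n",
    x$channel, x$feature, x$m, x$r, x$th))
  cat(sprintf("  mean MCC %.3f; repetition-best in %d repetitions\n",
              x$mean_mcc, x$n_top_reps))
  invisible(x)
}

#' Per-repetition performance of the selected optimum
#'
#' Scores the selected combination on every repetition's optimization and
#' validation subsets and summarizes each metric by its median and
#' interquartile range across repetitions.
#'
#' @param result A `cpvi_grid_result`.
#' @param selected A `cpvi_optimum` from [select_optimal()] (default:
#'   recomputed).
#' @return A list of class `cpvi_validation`: `per_rep` (data.frame with
#'   `repetition`, `subset`, and the six metrics) and `summary`
#'   (median / IQR per metric and subset).
#' @export
validate_selected <- function(result, selected = select_optimal(result)) {
  stopifnot(inherits(result, "cpvi_grid_result"))
  cb <- result$combos[selected$row, ]
  k <- which(result$combo4$m == cb$m & result$combo4$r == cb$r &
             result$combo4$feature == cb$feature &
             result$combo4$channel == cb$channel)
  pred <- result$pc[, k] > cb$th
  labels <- result$manifest$label
  rows <- list()
  for (rp in seq_along(result$splits)) {
    for (side in c("optimization", "validation")) {
      idx <- if (side == "optimization") result$splits[[rp]]$opt
             else result$splits[[rp]]$val
      keep <- idx[!is.na(pred[idx]) & !is.na(labels[idx])]
      pf <- performance(confusion(pred[keep], labels[keep]))
      rows[[length(rows) + 1L]] <- data.frame(
        repetition = rp, subset = side, mcc = pf$mcc,
        sensitivity = pf$sensitivity, specificity = pf$specificity,
        accuracy = pf$accuracy, ppv = pf$ppv, npv = pf$npv,
        stringsAsFactors = FALSE)
    }
  }
  per_rep <- do.call(rbind, rows)
  metrics <- c("mcc", "sensitivity", "specificity", "accuracy", "ppv",
               "npv")
  summ <- list()
  for (side in c("optimization", "validation")) {
    sub <- per_rep[per_rep$subset == side, ]
    for (mt in metrics) {
      v <- sub[[mt]]
      summ[[length(summ) + 1L]] <- data.frame(
        subset = side, metric = mt,
        median = stats::median(v, na.rm = TRUE),
        q25 = unname(stats::quantile(v, 0.25, na.rm = TRUE)),
        q75 = unname(stats::quantile(v, 0.75, na.rm = TRUE)),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(per_rep = per_rep, summary = do.call(rbind, summ),
                 selected = selected),
            class = "cpvi_validation")
}

#' Tolerance sensitivity scan around the selected optimum
#'
#' Re-runs the Sample Entropy computation on a fine tolerance grid
#' (default step 0.01 within `halfwidth` of the selected `r`), holding
#' `m`, `Th`, feature and channel at the optimum and reusing the same
#' repetition splits, and reports the mean optimization-subset MCC per
#' `r` — a check that the selected tolerance is a robust local maximum
#' rather than a knife-edge.
#'
#' @param corpus The `cpvi_corpus` the optimization ran on.
#' @param best A `cpvi_optimum`.
#' @param grid The [grid_spec()] used (supplies splits, seed, window
#'   settings).
#' @param step Grid step for `r` (default 0.01).
#' @param halfwidth Half-width of the scan (default 0.05; `best$r -
#'   halfwidth` must stay positive).
#' @return A data.frame `r`, `mean_mcc` with attribute `local_max`
#'   (logical: is the optimum's `r` a maximum of the scanned curve).
#' @export
r_sensitivity <- function(corpus, best, grid, step = 0.01,
                          halfwidth = 0.05) {
  stopifnot(inherits(best, "cpvi_optimum"), inherits(grid, "grid_spec"))
  if (best$r - halfwidth <= 0) {
    stop("halfwidth too large: r grid would reach 0", call. = FALSE)
  }
  r_values <- round(seq(best$r - halfwidth, best$r + halfwidth,
                        by = step), 10)
  sub_grid <- grid_spec(m_values = best$m, r_values = r_values,
                        th_values = best$th, features = best$feature,
                        channels = best$channel,
                        n_repeats = grid$n_repeats,
                        opt_fraction = grid$opt_fraction,
                        seed = grid$seed, window_s = grid$window_s,
                        overlap_frac = grid$overlap_frac,
                        ema_span = grid$ema_span,
                        min_defined = grid$min_defined)
  cache <- build_se_cache(corpus, sub_grid)
  res <- grid_search(cache, sub_grid)
  out <- data.frame(r = res$combos$r, mean_mcc = res$combos$mean_mcc)
  out <- out[order(out$r), , drop = FALSE]
  rownames(out) <- NULL
  at_best <- out$mean_mcc[which.min(abs(out$r - best$r))]
  attr(out, "local_max") <- at_best >= max(out$mean_mcc) - 1e-12
  out
}

#' End-to-end optimization of the CP-VI detector on a corpus
#'
#' Convenience wrapper: [build_se_cache()] then [grid_search()],
#' [select_optimal()] and [validate_selected()]. Deterministic under a
#' fixed `grid$seed`.
#'
#' @param corpus A `cpvi_corpus`.
#' @param grid A [grid_spec()].
#' @return A list of class `cpvi_optimization`: `result` (grid result),
#'   `optimum`, `validation`.
#' @export
run_optimization <- function(corpus, grid = grid_spec()) {
  cache <- build_se_cache(corpus, grid)
  result <- grid_search(cache, grid)
  optimum <- select_optimal(result)
  validation <- validate_selected(result, optimum)
  structure(list(result = result, optimum = optimum,
                 validation = validation),
            class = "cpvi_optimization")
}

#' @export
print.cpvi_optimization <- function(x, ...) {
  print(x$optimum)
  v <- x$validation$summary
  vv <- v[v$subset == "validation" & v$metric %in% c("mcc", "accuracy"), ]
  cat(sprintf("  validation median MCC %.3f, accuracy %.3f\n",
              vv$median[vv$metric == "mcc"],
              vv$median[vv$metric == "accuracy"]))
  invisible(x)
}
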