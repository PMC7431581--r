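#' Confusion counts against a gold standard
#'
#' Tallies the 2x2 confusion matrix of binary predictions against binary
#' gold-standard labels. Pairs where either value is `NA` (e.g. an
#' unevaluable segment) are dropped with a warning.
#'
#' @param pred Binary (0/1 or logical) predictions.
#' @param gold Binary gold-standard labels, same length.
#' @return An object of class `confusion_counts`: list with `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion <- function(pred, gold) {
  if (length(pred) != length(gold)) {
    stop("pred and gold must have equal length", call. = FALSE)
  }
  pred <- as.logical(pred); gold <- as.logical(gold)
  keep <- !is.na(pred) & !is.na(gold)
  if (!all(keep)) {
    warning(sum(!keep), " unevaluable pair(s) excluded from confusion",
            call. = FALSE)
    pred <- pred[keep]; gold <- gold[keep]
  }
  if (length(pred) == 0L) stop("no evaluable pairs", call. = FALSE)
  structure(list(tp = sum(pred & gold), tn = sum(!pred & !gold),
                 fp = sum(pred & !gold), fn = sum(!pred & gold)),
            class = "confusion_counts")
}

as_confusion <- function(x) {
  if (inherits(x, "confusion_counts")) return(x)
  stopifnot(is.numeric(x), all(c("tp", "tn", "fp", "fn") %in% names(x)))
  structure(as.list(x[c("tp", "tn", "fp", "fn")]),
            class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the balanced
#' single-number summary of a 2x2 confusion matrix, in `[-1, 1]`: 1 is
#' perfect agreement with the gold standard, -1 perfect disagreement, 0 no
#' better than chance. When any denominator factor is zero the MCC is
#' defined as 0 (the standard convention).
#'
#' @param c A `confusion_counts` object (or named vector with `tp`, `tn`,
#'   `fp`, `fn`).
#' @return A number in `[-1, 1]`.
#' @export
mcc <- function(c) {
  c <- as_confusion(c)
  tp <- as.numeric(c$tp); tn <- as.numeric(c$tn)
  fp <- as.numeric(c$fp); fn <- as.numeric(c$fn)
  if (tp + tn + fp + fn == 0) stop("empty confusion counts", call. = FALSE)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Diagnostic performance of a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive and
#' negative predictive values, accuracy, and [mcc()]. Ratios with a zero
#' denominator are reported as `NA` and should be excluded from
#' aggregation.
#'
#' @inheritParams mcc
#' @return A named list of class `performance_metrics`.
#' @export
performance <- function(c) {
  c <- as_confusion(c)
  tp <- c$tp; tn <- c$tn; fp <- c$fp; fn <- c$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion counts", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    accuracy = (tp + tn) / total,
    mcc = mcc(c),
    n = total), class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf(
    "Se %.3f  Sp %.3f  PPV %s  NPV %s  Acc %.3f  MCC %.3f  (n = %d)\n",
    x$sensitivity, x$specificity,
    ifelse(is.na(x$ppv), "NA", sprintf("%.3f", x$ppv)),
    ifelse(is.na(x$npv), "NA", sprintf("%.3f", x$npv)),
    x$accuracy, x$mcc, x$n))
  invisible(x)
}

#' Fleiss' kappa for multi-rater agreement
#'
#' Chance-corrected agreement among a fixed number of raters assigning
#' categorical labels to the same set of items:
#' `kappa = (Pbar - Pbar_e) / (1 - Pbar_e)` where `Pbar` is the mean
#' observed pairwise agreement per item and `Pbar_e` the agreement
#' expected from the marginal category frequencies.
#'
#' @param ratings A matrix (items x raters) of categorical labels (any
#'   atomic type), no missing values, >= 2 raters and >= 2 items.
#' @return Fleiss' kappa; 1 for unanimous ratings.
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) {
    stop("missing ratings: every item needs the same rater count",
         call. = FALSE)
  }
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) {
    stop("need >= 2 items and >= 2 raters", call. = FALSE)
  }
  cats <- sort(unique(as.vector(ratings)))
  counts <- vapply(cats, function(cg) rowSums(ratings == cg),
                   numeric(n))
  counts <- matrix(counts, nrow = n)
  p_i <- (rowSums(counts^2) - k) / (k * (k - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (n * k)
  p_e <- sum(p_j^2)
  if (p_e == 1) return(1)  # single category used throughout: unanimity
  (p_bar - p_e) / (1 - p_e)
}

#' Performance stratified by ventilation mode (or any grouping)
#'
#' Computes [performance()] within each stratum of segments; empty strata
#' are omitted with a warning.
#'
#' @param pred,gold Binary vectors as in [confusion()].
#' @param strata Stratum label per segment (e.g. `"PSV"` / `"ACV"`).
#' @return A named list of `performance_metrics`, one per stratum.
#' @export
stratified_performance <- function(pred, gold, strata) {
  if (length(strata) != length(pred)) {
    stop("strata must label every segment", call. = FALSE)
  }
  out <- list()
  for (s in unique(strata)) {
    idx <- which(strata == s & !is.na(pred) & !is.na(gold))
    if (length(idx) == 0L) {
      warning("stratum '", s, "' has no evaluable segments; omitted",
              call. = FALSE)
      next
    }
    out[[as.character(s)]] <- performance(confusion(pred[idx], gold[idx]))
  }
  out
}
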