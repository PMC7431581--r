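# Independent reference implementations used as oracles. These follow the
# definitions directly and share no code with the package's optimized
# paths.

# Sample Entropy by direct template counting: templates X_m(i), i = 1..N-m,
# self-matches excluded, B = m-length match pairs, A = (m+1)-length match
# pairs over the same index range.
sampen_naive <- function(x, m, r) {
  N <- length(x)
  nt <- N - m
  B <- 0; A <- 0
  for (i in seq_len(nt)) {
    dm <- rep(0, nt)
    dm1 <- rep(0, nt)
    for (k in 0:(m - 1)) {
      dm <- pmax(dm, abs(x[i + k] - x[k + seq_len(nt)]))
    }
    dm1 <- pmax(dm, abs(x[i + m] - x[m + seq_len(nt)]))
    dm[i] <- Inf; dm1[i] <- Inf  # exclude self-match
    B <- B + sum(dm <= r)
    A <- A + sum(dm1 <= r)
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# Straight-line re-implementation of the CP-VI decision rule: explicit
# state machine over ordered segment features.
detect_oracle <- function(values, th) {
  baseline <- NA_real_
  out <- data.frame(pc = rep(NA_real_, length(values)),
                    cpvi = rep(NA, length(values)))
  for (i in seq_along(values)) {
    v <- values[i]
    if (is.na(v)) next
    if (is.na(baseline)) baseline <- v
    out$pc[i] <- 100 * (v - baseline) / baseline
    out$cpvi[i] <- out$pc[i] > th
    if (v < baseline) baseline <- v
  }
  out
}

# Step-by-step Fleiss' kappa from the category count table.
fleiss_oracle <- function(counts) {
  n <- nrow(counts); k <- sum(counts[1, ])
  p_i <- (rowSums(counts^2) - k) / (k * (k - 1))
  p_j <- colSums(counts) / (n * k)
  (mean(p_i) - sum(p_j^2)) / (1 - sum(p_j^2))
}

# 20-segment x 3-rater agreement fixture: alternating true labels with a
# 10% per-rater flip probability (seed 42). Expected kappa frozen from an
# independent implementation (statsmodels.stats.inter_rater.fleiss_kappa).
fleiss_fixture <- function() {
  set.seed(42)
  truth <- rep(c(1, 0), 10)
  flip <- function(x) ifelse(runif(20) < 0.1, 1 - x, x)
  cbind(flip(truth), flip(truth), flip(truth))
}
FLEISS_FIXTURE_KAPPA <- 0.725714285714286

# Small labeled corpus shared by the slower end-to-end tests.
tiny_corpus <- function(n = 4, seed = 7, duration_min = 30) {
  make_benchmark_corpus(n_recordings = n, seed = seed,
                        duration_min = duration_min)
}
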