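fake_series <- function(values, times) {
  s <- data.frame(time_s = times, se_raw = values, se = values,
                  defined = !is.na(values))
  class(s) <- c("se_series", "data.frame")
  attr(s, "channel") <- "flow"
  s
}

fake_segments <- function(bounds) {
  s <- data.frame(index = seq_len(length(bounds) - 1),
                  start_s = bounds[-length(bounds)], end_s = bounds[-1],
                  label = NA_integer_, mode = "PSV")
  class(s) <- c("cpvi_segments", "data.frame")
  s
}

test_that("segment features aggregate defined SE points by window centre", {
  segs <- fake_segments(c(0, 900, 1800))
  s <- fake_series(c(rep(1.2, 30), 0.5, 1.0, 1.5, rep(NA, 27)),
                   times = c(seq(15, 890, length.out = 30),
                             seq(915, 1790, length.out = 30)))
  fmax <- segment_features(s, segs, "max", min_defined = 3)
  expect_equal(fmax$value[1], 1.2)
  fmean <- segment_features(s, segs, "mean", min_defined = 3)
  expect_equal(fmean$value[2], 1.0)
  expect_equal(fmean$n_defined, c(30, 3))
  # below the defined-point minimum -> unevaluable, not an error
  few <- segment_features(s, segs, "mean", min_defined = 10)
  expect_true(is.na(few$value[2]))
  expect_false(few$evaluable[2])
})

test_that("windows straddling a boundary follow their centre", {
  segs <- fake_segments(c(0, 900, 1800))
  s <- fake_series(c(1, 9), times = c(899.9, 900.1))
  f <- segment_features(s, segs, "max", min_defined = 1)
  expect_equal(f$value, c(1, 9))
})

test_that("baseline state follows first-value initialization and running min", {
  st <- baseline_state()
  st <- update_baseline(st, 1.4)
  expect_equal(st$baseline, 1.4)
  expect_equal(update_baseline(st, 1.6)$baseline, 1.4)
  expect_equal(update_baseline(st, 1.1)$baseline, 1.1)
  expect_identical(update_baseline(st, NA_real_), st)
})

test_that("percent change is the relative departure from baseline", {
  st <- baseline_state(1.0, TRUE)
  expect_equal(percent_change(1.3, st), 30)
  expect_equal(percent_change(1.0, st), 0)
  expect_equal(percent_change(0.8, st), -20)
  expect_error(percent_change(1, baseline_state()), "not initialized")
  expect_error(percent_change(1, baseline_state(0, TRUE)), "not positive")
})

test_that("detection flags strictly above threshold against the evolving
           baseline", {
  flat <- detect_cpvi(c(1, 1, 1), th = 25)
  expect_equal(flat$cpvi, rep(FALSE, 3))
  d <- detect_cpvi(c(1.0, 1.3, 1.0), th = 25)
  expect_equal(d$cpvi, c(FALSE, TRUE, FALSE))
  expect_equal(d$pc, c(0, 30, 0))
  # a tie at exactly Th is negative
  tie <- detect_cpvi(c(1.0, 1.25), th = 25)
  expect_equal(tie$cpvi, c(FALSE, FALSE))
  # the first segment defines the baseline, so it can never be flagged
  d2 <- detect_cpvi(c(5, 1, 1.2), th = 10)
  expect_false(d2$cpvi[1])
  expect_error(detect_cpvi(numeric(0), 25), "empty")
})

test_that("unevaluable segments are skipped without touching the baseline", {
  d <- detect_cpvi(c(1.0, NA, 1.3), th = 25)
  expect_true(is.na(d$cpvi[2]))
  expect_equal(d$pc[3], 30)
})

test_that("seeding the baseline from the first k segments is available", {
  # a CP-VI-containing first segment would inflate the baseline; k = 2
  # guards by taking the minimum over the first two
  d <- detect_cpvi(c(2.0, 1.0, 1.4), th = 25, baseline_init_k = 2)
  expect_equal(d$baseline_used, c(1.0, 1.0, 1.0))
  expect_equal(d$cpvi, c(TRUE, FALSE, TRUE))
})

test_that("detection agrees with an independent straight-line oracle", {
  set.seed(11)
  for (i in 1:30) {
    v <- runif(12, 0.5, 2)
    v[sample(12, 2)] <- NA
    th <- sample(seq(15, 50, 5), 1)
    d <- detect_cpvi(v, th)
    o <- detect_oracle(v, th)
    expect_equal(d$pc, o$pc)
    expect_equal(d$cpvi, o$cpvi)
    # and with the vectorized percent-change path used by the grid search
    expect_equal(cpvi:::pc_sequence(v), o$pc)
  }
})

test_that("detection count is monotone in the threshold and scale-free", {
  set.seed(12)
  for (i in 1:10) {
    v <- runif(10, 0.5, 2)
    counts <- sapply(seq(15, 50, 5),
                     function(th) sum(detect_cpvi(v, th)$cpvi))
    expect_true(all(diff(counts) <= 0))
    for (c_ in c(0.1, 3)) {
      expect_equal(detect_cpvi(c_ * v, 25)$cpvi, detect_cpvi(v, 25)$cpvi)
      expect_equal(detect_cpvi(c_ * v, 25)$pc, detect_cpvi(v, 25)$pc)
    }
    # baseline equals the running minimum of earlier features
    d <- detect_cpvi(v, 25)
    expect_equal(d$baseline_used[-1], cummin(v)[-length(v)])
  }
})
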