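test_that("chebyshev distance matches its definition", {
  expect_equal(chebyshev_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(chebyshev_distance(c(0, 0), c(3, -4)), 4)
  expect_error(chebyshev_distance(1:3, 1:2), "equal length")
  set.seed(1)
  for (i in 1:25) {
    m <- sample(1:8, 1)
    u <- rnorm(m); v <- rnorm(m)
    naive <- 0
    for (k in seq_len(m)) naive <- max(naive, abs(u[k] - v[k]))
    expect_identical(chebyshev_distance(u, v), naive)
  }
})

test_that("sample entropy handles canonical inputs", {
  # constant vector: every template matches at m and m+1, A/B = 1, SE = 0
  expect_identical(sample_entropy(rep(1, 100), m = 2, r_abs = 0.1), 0)
  # strict alternation: value frozen from the naive template counter
  x <- c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2)
  expect_equal(sample_entropy(x, 2, 0.5), sampen_naive(x, 2, 0.5),
               tolerance = 1e-12)
  expect_error(sample_entropy(1:4, 2, 0.1), "length")
  expect_error(sample_entropy(c(1, NA, 3, 4, 5, 6), 2, 0.1), "finite")
  expect_error(sample_entropy(rnorm(50), 2, -1), "positive")
})

test_that("optimized kernel equals the naive counter on random series", {
  set.seed(10)
  for (i in 1:40) {
    N <- sample(20:120, 1)
    m <- sample(1:5, 1)
    x <- rnorm(N)
    r <- sample(c(0.1, 0.2, 0.3, 0.4), 1) * sd(x)
    expect_equal(sample_entropy(x, m, r), sampen_naive(x, m, r),
                 tolerance = 1e-10)
  }
})

test_that("SE is nonnegative and non-increasing in the tolerance", {
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(150)
    vals <- sapply(seq(0.1, 0.6, by = 0.1) * sd(x),
                   function(r) sample_entropy(x, 2, r))
    defined <- vals[!is.na(vals)]
    expect_true(all(defined >= 0))
    expect_true(all(diff(vals[!is.na(vals)]) <= 1e-12))
  }
})

test_that("shuffling a sine does not decrease its sample entropy", {
  t <- seq(0, 20, length.out = 400)
  x <- sin(2 * pi * t)
  se_sine <- sample_entropy(x, 2, 0.2 * sd(x))
  for (seed in 1:20) {
    set.seed(seed)
    xs <- sample(x)
    se_shuf <- sample_entropy(xs, 2, 0.2 * sd(xs))
    expect_gte(se_shuf, se_sine)
  }
})

test_that("sliding series has the documented window grid", {
  set.seed(2)
  x <- rnorm(900 * 40)  # 15 min at 40 Hz
  s <- se_sliding_series(x, se_params(2, 0.2))
  expect_equal(nrow(s), 59)  # floor((900 - 30) / 15) + 1
  expect_equal(diff(s$time_s), rep(15, 58))
  expect_equal(s$time_s[1], 15)  # centre of the first 30-s window
  expect_true(all(s$defined))
  # constant channel: SD = 0 in every window -> undefined throughout
  sc <- se_sliding_series(rep(2, 900 * 40), se_params(2, 0.2))
  expect_true(all(is.na(sc$se)))
  expect_error(se_sliding_series(rnorm(100), se_params()), "one window")
})

test_that("SE series steps upward at a slow-to-fast transition", {
  t1 <- seq(0, 450 - 1 / 40, by = 1 / 40)
  slow <- sin(2 * pi * 0.2 * t1)
  fast <- sin(2 * pi * 1.1 * t1)
  s <- se_sliding_series(c(slow, fast), se_params(2, 0.2, smoothing_on = FALSE))
  n <- nrow(s)
  first <- mean(s$se[1:10], na.rm = TRUE)
  last <- mean(s$se[(n - 9):n], na.rm = TRUE)
  expect_gt(last, first)
})

test_that("EMA smoothing follows the recursive definition", {
  expect_equal(ema_smooth(rep(2.5, 20), span = 8), rep(2.5, 20))
  x <- rnorm(30)
  expect_equal(ema_smooth(x, span = 1), x)
  # unit impulse: geometric decay with ratio 1 - alpha
  imp <- c(1, rep(0, 9))
  alpha <- 2 / (8 + 1)
  expect_equal(ema_smooth(imp, span = 8), (1 - alpha)^(0:9),
               tolerance = 1e-12)
  expect_error(ema_smooth(numeric(0), 8), "empty")
  expect_error(ema_smooth(1:5, 0), "positive integer")
})

test_that("EMA skips undefined points and is bounded by its inputs", {
  x <- c(1, NA, 3, NA, NA, 2)
  y <- ema_smooth(x, span = 3)
  expect_true(all(is.na(y[is.na(x)])))
  # state carried across the gap: y[3] uses y[1], not a reset
  alpha <- 2 / 4
  expect_equal(y[3], alpha * 3 + (1 - alpha) * 1)
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(50)
    x[sample(50, 8)] <- NA
    y <- ema_smooth(x, span = sample(2:10, 1))
    expect_true(all(y >= min(x, na.rm = TRUE) - 1e-12, na.rm = TRUE))
    expect_true(all(y <= max(x, na.rm = TRUE) + 1e-12, na.rm = TRUE))
  }
})

test_that("the grid computation agrees with the single-setting path", {
  set.seed(8)
  x <- rnorm(60 * 40)
  g <- se_sliding_grid(x, m_values = c(2, 4), r_values = c(0.2, 0.3),
                       smoothing_on = TRUE)
  for (m in c(2, 4)) for (r in c(0.2, 0.3)) {
    s <- se_sliding_series(x, se_params(m, r))
    expect_equal(as.numeric(g$se[as.character(m), as.character(r), ]),
                 s$se, tolerance = 1e-12)
  }
})
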