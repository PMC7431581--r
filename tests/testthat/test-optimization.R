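# A hand-crafted SE feature cache where the detection answer is known by
# construction: per recording the running-min baseline is the first
# segment's 1.0, "benign" segments sit at PC = 22 (negative) and true
# CP-VI segments at PC = 28 or 60 (positive), so Th = 25 is the unique
# separating threshold on the grid: 15/20 suffer false positives, 30+
# suffer false negatives.
crafted_cache <- function(n_rec = 8, grid = grid_spec(
                            m_values = 2L, r_values = 0.2,
                            features = "max", channels = "flow",
                            n_repeats = 15, seed = 5)) {
  v_pat <- list(c(1.0, 1.28, 1.22, 1.0), c(1.0, 1.6, 1.0, 1.28),
                c(1.0, 1.0, 1.22, 1.28))
  l_pat <- list(c(0L, 1L, 0L, 0L), c(0L, 1L, 0L, 1L), c(0L, 0L, 0L, 1L))
  vals <- labs <- c()
  for (i in seq_len(n_rec)) {
    k <- 1 + (i - 1) %% 3
    vals <- c(vals, v_pat[[k]])
    labs <- c(labs, l_pat[[k]])
  }
  manifest <- data.frame(
    recording_id = rep(sprintf("r%02d", seq_len(n_rec)), each = 4),
    segment_index = rep(1:4, n_rec), label = labs,
    mode = "PSV", stringsAsFactors = FALSE)
  feats <- array(rep(vals, length(grid$m_values) * length(grid$r_values)),
                 dim = c(length(vals), 1, 1, length(grid$m_values),
                         length(grid$r_values)),
                 dimnames = list(NULL, grid$channels, grid$features,
                                 grid$m_values, grid$r_values))
  structure(list(features = feats, manifest = manifest, grid = grid),
            class = "se_cache")
}

test_that("holdout split is exhaustive, sized by rounding, reproducible", {
  labels <- rep(c(1, 0), c(49, 43))  # 92 segments
  sp <- holdout_split(labels, 0.70, seed = 3)
  expect_equal(length(sp$opt), 64)
  expect_equal(length(sp$val), 28)
  expect_setequal(c(sp$opt, sp$val), seq_along(labels))
  expect_identical(sp, holdout_split(labels, 0.70, seed = 3))
  sp2 <- holdout_split(rep(c(0, 1), 5), 0.5, seed = 1)
  expect_equal(length(sp2$opt), 5)
  expect_error(holdout_split(rep(1, 10), 0.7, 1), "one class")
  strat <- holdout_split(rep(c(0, 1), c(40, 20)), 0.70, seed = 2,
                         stratify = TRUE)
  expect_equal(sum(strat$opt <= 40), 28)  # round(0.7 * 40)
  expect_equal(sum(strat$opt > 40), 14)
})

test_that("the default single-channel grid evaluates 640 combinations", {
  grid <- grid_spec(channels = "flow", features = "max", n_repeats = 2,
                    seed = 1)
  # the crafted feature slice replicated across the full (m, r) grid
  cache <- crafted_cache(n_rec = 3, grid = grid)
  res <- grid_search(cache, grid)
  expect_equal(nrow(res$combos), 20 * 4 * 8)
  expect_equal(ncol(res$rep_mcc), 2)
})

test_that("a degenerate one-point grid reduces to a single detect+score", {
  grid <- grid_spec(m_values = 2L, r_values = 0.2, th_values = 25,
                    features = "max", channels = "flow", n_repeats = 1,
                    seed = 9)
  cache <- crafted_cache(grid = grid)
  res <- grid_search(cache, grid)
  expect_equal(nrow(res$combos), 1)
  v <- cache$features[, 1, 1, 1, 1]
  pred <- unlist(lapply(split(seq_along(v), cache$manifest$recording_id),
                        function(idx) detect_cpvi(v[idx], 25)$cpvi))
  idx <- res$splits[[1]]$opt
  expect_equal(res$rep_mcc[1, 1],
               mcc(confusion(pred[idx], cache$manifest$label[idx])))
})

test_that("the grid search recovers the constructed separating threshold", {
  grid <- grid_spec(m_values = 2L, r_values = 0.2, features = "max",
                    channels = "flow", n_repeats = 15, seed = 5)
  cache <- crafted_cache(grid = grid)
  res <- grid_search(cache, grid)
  opt <- select_optimal(res)
  expect_equal(opt$th, 25)
  expect_equal(opt$mean_mcc, 1)
  expect_equal(opt$n_top_reps, 15)
  by_th <- tapply(res$combos$mean_mcc, res$combos$th, max)
  expect_true(all(by_th[c("15", "20", "30", "50")] < 1))
  # perfect-by-construction detector: all validation medians are 1
  val <- validate_selected(res, opt)
  expect_equal(unname(val$summary$median), rep(1, 12))
})

test_that("selection ties break toward smaller m, then r, then Th", {
  combos <- expand.grid(m = c(2L, 5L), r = c(0.2, 0.3), th = c(25, 30),
                        feature = "max", channel = "flow",
                        stringsAsFactors = FALSE)
  combos$mean_mcc <- 0.9
  combos$mean_mcc[combos$m == 5 & combos$r == 0.2 & combos$th == 25] <- 0.95
  fake <- structure(list(combos = combos,
                         rep_mcc = matrix(combos$mean_mcc, nrow(combos), 3)),
                    class = "cpvi_grid_result")
  opt <- select_optimal(fake)
  expect_equal(c(opt$m, opt$r, opt$th), c(5, 0.2, 25))
  combos$mean_mcc <- 0.9  # full tie: parsimony picks the smallest triple
  fake$combos <- combos
  opt2 <- select_optimal(fake)
  expect_equal(c(opt2$m, opt2$r, opt2$th), c(2, 0.2, 25))
  # randomized surfaces: argmax equals an exhaustive scan
  set.seed(31)
  for (i in 1:20) {
    combos$mean_mcc <- runif(nrow(combos))
    fake$combos <- combos
    best <- select_optimal(fake)
    expect_equal(best$mean_mcc, max(combos$mean_mcc))
  }
})

test_that("cached features equal a direct recomputation from waveforms", {
  corpus <- tiny_corpus(n = 4, seed = 7)
  grid <- grid_spec(m_values = c(2L, 4L), r_values = c(0.2, 0.3),
                    features = c("max", "mean"), channels = "flow",
                    n_repeats = 3, seed = 7)
  cache <- build_se_cache(corpus, grid)
  for (spot in list(c(2, 0.2, "max"), c(4, 0.3, "mean"),
                    c(2, 0.3, "max"))) {
    m <- as.integer(spot[1]); r <- as.numeric(spot[2]); kind <- spot[3]
    id <- corpus$manifest$recording_id[5]
    rec <- decimate_to_40hz(corpus$recordings[[id]])
    series <- se_sliding_series(rec, se_params(m, r), channel = "flow")
    segs <- partition_segments(rec, 15)
    f <- segment_features(series, segs, kind)
    got <- cache$features[cache$manifest$recording_id == id, "flow",
                          kind, as.character(m), as.character(r)]
    expect_equal(unname(got), f$value, tolerance = 1e-12)
  }
})

test_that("the full optimization is deterministic under its master seed", {
  corpus <- tiny_corpus(n = 4, seed = 7)
  grid <- grid_spec(m_values = c(1L, 2L), r_values = c(0.2, 0.4),
                    features = "max", channels = "flow", n_repeats = 4,
                    seed = 11)
  r1 <- run_optimization(corpus, grid)
  r2 <- run_optimization(corpus, grid)
  expect_identical(r1$result$combos, r2$result$combos)
  expect_identical(r1$result$rep_mcc, r2$result$rep_mcc)
  expect_identical(r1$optimum, r2$optimum)
  expect_identical(r1$validation$per_rep, r2$validation$per_rep)
})

test_that("the tolerance sensitivity scan covers the documented grid", {
  corpus <- tiny_corpus(n = 4, seed = 7)
  grid <- grid_spec(m_values = 2L, r_values = 0.2, th_values = 25,
                    features = "max", channels = "flow", n_repeats = 3,
                    seed = 7)
  best <- structure(list(channel = "flow", feature = "max", m = 2L,
                         r = 0.2, th = 25), class = "cpvi_optimum")
  curve <- r_sensitivity(corpus, best, grid, step = 0.01,
                         halfwidth = 0.05)
  expect_equal(nrow(curve), 11)
  expect_equal(curve$r, seq(0.15, 0.25, by = 0.01))
  expect_true(all(curve$mean_mcc >= -1 & curve$mean_mcc <= 1))
  expect_type(attr(curve, "local_max"), "logical")
  curve2 <- r_sensitivity(corpus, best, grid, step = 0.01,
                          halfwidth = 0.05)
  expect_identical(curve, curve2)
  expect_error(r_sensitivity(corpus, best, grid, halfwidth = 0.3),
               "halfwidth")
})
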