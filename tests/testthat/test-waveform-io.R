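make_rec <- function(n = 1200, rate = 40, seed = 1) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / rate
  waveform_recording(flow = 30 * sin(2 * pi * 0.3 * t) + rnorm(n),
                     paw = 10 + 5 * sin(2 * pi * 0.3 * t) + rnorm(n),
                     rate = rate, mode = "PSV")
}

test_that("recording construction enforces the container invariants", {
  expect_error(waveform_recording(1:3, 1:2, 40), "equal length")
  expect_error(waveform_recording(numeric(0), numeric(0), 40), "empty")
  expect_error(waveform_recording(c(1, NA), c(1, 2), 40), "missing")
  expect_error(waveform_recording(1:2, 1:2, -1), "rate")
  rec <- make_rec(100)
  expect_s3_class(rec, "waveform_recording")
  expect_equal(duration_s(rec), 2.5)
})

test_that("CSV round trip reproduces samples bit-exactly", {
  rec <- make_rec(500)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording(path, mode = "PSV")
  expect_identical(back$flow, rec$flow)
  expect_identical(back$paw, rec$paw)
  expect_equal(back$rate, rec$rate, tolerance = 1e-12)
})

test_that("malformed recording files raise the documented errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,flow_lpm", "0,1", "0.025,2"), path)
  expect_error(read_recording(path), "paw")
  # a 2-second gap in otherwise uniform timestamps
  t <- c(seq(0, 1, by = 0.025), seq(3, 4, by = 0.025))
  df <- data.frame(time_s = t, flow_lpm = seq_along(t),
                   paw_cmh2o = seq_along(t))
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_recording(path), "sampling error")
  writeLines("time_s,flow_lpm,paw_cmh2o", path)
  expect_error(read_recording(path), "empty")
  expect_error(read_recording(tempfile(fileext = ".csv")), "not found")
})

test_that("EDF round trip maps channels by label and preserves values to
           quantization accuracy", {
  rec <- make_rec(n = 400, rate = 40)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path, format = "edf", mode = "PSV")
  expect_equal(back$rate, 40)
  expect_equal(length(back$flow), 400)
  # 16-bit quantization over the written physical range
  step_flow <- diff(range(rec$flow)) / 65535 + 2 / 65535
  expect_lt(max(abs(back$flow - rec$flow)), 20 * step_flow)
  expect_lt(max(abs(back$paw - rec$paw)), 20 * step_flow)
})

test_that("decimation has the documented length, rate and phase", {
  set.seed(3)
  n <- 24000
  t <- (seq_len(n) - 1) / 200
  rec <- waveform_recording(flow = rnorm(n), paw = rnorm(n), rate = 200)
  dec <- decimate_to_40hz(rec)
  expect_equal(dec$rate, 40)
  expect_equal(length(dec$flow), 4800)
  # identity at 40 Hz
  rec40 <- make_rec(100, rate = 40)
  expect_identical(decimate_to_40hz(rec40), rec40)
  # unsupported rates
  rec100 <- waveform_recording(rnorm(100), rnorm(100), rate = 100)
  expect_error(decimate_to_40hz(rec100), "unsupported rate")
})

test_that("decimated in-band sine matches its analytic samples, zero phase", {
  n <- 24000
  t_in <- (seq_len(n) - 1) / 200
  rec <- waveform_recording(flow = sin(2 * pi * 5 * t_in),
                            paw = cos(2 * pi * 5 * t_in), rate = 200)
  dec <- decimate_to_40hz(rec)
  t_out <- (seq_along(dec$flow) - 1) / 40
  interior <- t_out > 0.5 & t_out < max(t_out) - 0.5
  expect_lt(max(abs(dec$flow[interior] - sin(2 * pi * 5 * t_out[interior]))),
            0.01)
  expect_lt(max(abs(dec$paw[interior] - cos(2 * pi * 5 * t_out[interior]))),
            0.01)
})

test_that("decimation maps a constant signal to the same constant", {
  rec <- waveform_recording(flow = rep(3.5, 2000), paw = rep(12, 2000),
                            rate = 200)
  dec <- decimate_to_40hz(rec)
  expect_lt(max(abs(dec$flow - 3.5)), 1e-9)
  expect_lt(max(abs(dec$paw - 12)), 1e-9)
})

test_that("segment partitioning tiles the recording and drops remainders", {
  rec120 <- waveform_recording(rnorm(120 * 60 * 40), rnorm(120 * 60 * 40),
                               rate = 40)
  segs <- partition_segments(rec120, 15)
  expect_equal(nrow(segs), 8)
  expect_equal(segs$end_s - segs$start_s, rep(900, 8))
  expect_equal(segs$start_s[-1], segs$end_s[-8])  # contiguous tiling
  rec15 <- waveform_recording(rnorm(900 * 40), rnorm(900 * 40), rate = 40)
  expect_equal(nrow(partition_segments(rec15, 15)), 1)
  rec37 <- waveform_recording(rnorm(37 * 60 * 40), rnorm(37 * 60 * 40),
                              rate = 40)
  expect_message(s37 <- partition_segments(rec37, 15), "remainder")
  expect_equal(nrow(s37), 2)
  rec10 <- waveform_recording(rnorm(10 * 60 * 40), rnorm(10 * 60 * 40),
                              rate = 40)
  expect_error(partition_segments(rec10, 15), "shorter")
})
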