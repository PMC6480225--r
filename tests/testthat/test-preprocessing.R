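# Frequency-response oracle: evaluate the designed taps' transfer function
# at f Hz directly from the DTFT, independently of the filtering code path.
tap_response <- function(taps, f_hz, fs) {
  k <- seq_along(taps) - 1
  Mod(sum(taps * exp(-2i * pi * f_hz * k / fs)))
}

rms <- function(x) sqrt(mean(x^2))

test_that("low-pass passes DC at unit gain", {
  y <- fir_lowpass(rep(5, 200), cutoff_hz = 10, sampling_hz = 50)
  expect_equal(length(y), 200)
  expect_lt(max(abs(y - 5)), 1e-6)
})

test_that("stop-band and pass-band attenuation match the designed response", {
  fs <- 50
  t <- (0:599) / fs
  taps <- fir_lowpass_taps(10, fs, 51)

  # compare on the interior so reflection-padding edge transients (one
  # filter length at each end) do not dominate the deep stop-band RMS
  core <- 52:548
  x20 <- sin(2 * pi * 20 * t)
  y20 <- fir_lowpass(x20, 10, fs)
  h20 <- tap_response(taps, 20, fs)
  ratio20 <- rms(y20[core]) / rms(x20[core])
  expect_lte(ratio20, 0.05)
  expect_lt(abs(ratio20 - h20), 0.1 * max(h20, ratio20))

  x2 <- sin(2 * pi * 2 * t)
  y2 <- fir_lowpass(x2, 10, fs)
  h2 <- tap_response(taps, 2, fs)
  ratio2 <- rms(y2[core]) / rms(x2[core])
  expect_lt(abs(ratio2 - 1), 0.05)
  expect_lt(abs(ratio2 - h2), 0.1 * h2)
})

test_that("filtering is zero-phase: a pass-band sinusoid is not delayed", {
  fs <- 50
  t <- (0:499) / fs
  x <- sin(2 * pi * 2 * t)
  y <- fir_lowpass(x, 10, fs)
  # compare interior samples (edges see the reflection padding)
  core <- 60:440
  expect_lt(max(abs(y[core] - x[core])), 0.02)
})

test_that("filter configuration is validated", {
  expect_error(fir_lowpass_taps(30, 50), "Nyquist")
  expect_error(fir_lowpass_taps(10, 50, n_taps = 50), "odd")
  expect_error(fir_lowpass(rnorm(20), 10, 50, n_taps = 51), "length")
})

test_that("the filter is linear", {
  set.seed(31)
  x <- rnorm(300); y <- rnorm(300)
  a <- 2.5; b <- -0.7
  lhs <- fir_lowpass(a * x + b * y, 10, 50)
  rhs <- a * fir_lowpass(x, 10, 50) + b * fir_lowpass(y, 10, 50)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("window arithmetic: 2.56 s at 50 Hz is 128 samples", {
  expect_identical(segment_window_samples(2.56, 50), 128L)
  expect_identical(segment_window_samples(2.56, 20), 51L)
})

test_that("segmentation window counts follow floor((n - w)/stride) + 1", {
  x <- matrix(rnorm(3 * 256), nrow = 3)
  expect_equal(dim(segment_stream(x[, 1:128], sampling_hz = 50,
                                  overlap_fraction = 0))[1], 1)
  expect_equal(dim(segment_stream(x, sampling_hz = 50,
                                  overlap_fraction = 0.5))[1], 3)
  # brute-force enumeration over assorted cases
  for (case in list(c(300, 50, 0), c(300, 50, 0.5), c(127, 40, 0.25))) {
    n <- case[1]; w <- case[2]; ov <- case[3]
    stride <- max(1, round(w * (1 - ov)))
    starts <- seq(1, n, by = stride)
    expected <- sum(starts + w - 1 <= n)
    got <- dim(segment_stream(matrix(rnorm(n), 1), sampling_hz = 1,
                              overlap_fraction = ov, window_samples = w))[1]
    expect_equal(got, expected)
  }
})

test_that("non-overlapping segmentation partitions the series exactly", {
  x <- matrix(seq_len(2 * 384), nrow = 2)
  win <- segment_stream(x, sampling_hz = 50, overlap_fraction = 0,
                        window_samples = 128)
  expect_equal(dim(win)[1], 3)
  reconstructed <- cbind(t(win[1, , ]), t(win[2, , ]), t(win[3, , ]))
  expect_equal(reconstructed, x, ignore_attr = TRUE)
})

test_that("too-short series yields zero windows with a warning", {
  expect_warning(
    out <- segment_stream(matrix(rnorm(50), 1), sampling_hz = 50,
                          window_samples = 128),
    "shorter")
  expect_equal(dim(out)[1], 0)
})

test_that("standardization centers and scales per channel without leakage", {
  d <- generate_dataset(5, default_specs("uci"), seed = 11)
  std <- standardize(d)
  for (ch in 1:6) {
    expect_lt(abs(mean(std$dataset$samples[, , ch])), 1e-10)
    expect_lt(abs(sd(std$dataset$samples[, , ch]) - 1), 1e-10)
  }
  # re-fit on standardized data is idempotent
  again <- standardize(std$dataset)
  expect_lt(max(abs(again$stats$mean)), 1e-10)
  expect_lt(max(abs(again$stats$sd - 1)), 1e-10)

  # a shifted test set keeps its shift under train-time stats
  shifted <- d
  shifted$samples[, , 1] <- shifted$samples[, , 1] + 3
  test_std <- standardize(shifted, std$stats)$dataset
  expect_gt(abs(mean(test_std$samples[, , 1])), 1)
})

test_that("constant channels standardize to zero, and the round trip inverts", {
  samples <- array(rnorm(4 * 16 * 6), c(4, 16, 6))
  samples[, , 2] <- 7
  d <- har_dataset(samples, labels = rep(0L, 4))
  expect_warning(std <- standardize(d), "zero-variance")
  expect_true(all(std$dataset$samples[, , 2] == 0))
  back <- unstandardize(std$dataset, std$stats)
  expect_lt(max(abs(back$samples - samples)), 1e-9)
})

test_that("stream tibbles segment into labeled datasets", {
  streams <- tibble::tibble(
    user_id = c(1L, 2L),
    activity = c("walking", "jogging"),
    xyz = list(matrix(rnorm(3 * 120), 3), matrix(rnorm(3 * 40), 3))
  )
  d <- segment_streams(streams, sampling_hz = 20, overlap_fraction = 0.5,
                       window_samples = 40)
  # stream 1: floor((120-40)/20)+1 = 5 windows; stream 2: 1 window
  expect_equal(n_windows(d), 6)
  expect_equal(window_counts(d)$n[window_counts(d)$name == "walking"], 5L)
  expect_equal(unique(d$subjects[d$labels == 1L]), 2L)
})
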