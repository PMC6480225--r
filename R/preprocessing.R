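#' FIR low-pass filter design and zero-phase application
#'
#' Sensor channels are smoothed with a linear-phase FIR low-pass filter
#' (Hamming-windowed sinc via [signal::fir1()]) before classification;
#' the default cut-off of 10 Hz keeps the band where voluntary human
#' movement lives while rejecting high-frequency sensor noise. The filter
#' is applied zero-phase: the signal is reflected at both ends, convolved
#' with the centred taps, and cropped back to its original length, so no
#' group delay is introduced and the output length equals the input length.
#'
#' @param x Numeric vector, one sensor channel.
#' @param cutoff_hz Cut-off frequency in Hz; must lie below the Nyquist
#'   frequency `sampling_hz / 2`.
#' @param sampling_hz Sampling rate of `x` in Hz.
#' @param n_taps Number of filter taps; odd so the group delay is an
#'   integer number of samples. Default 51.
#' @return Filtered numeric vector, same length as `x`.
#' @examples
#' t <- seq(0, 2, by = 1 / 50)
#' noisy <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 20 * t)
#' clean <- fir_lowpass(noisy, cutoff_hz = 10, sampling_hz = 50)
#' @export
fir_lowpass <- function(x, cutoff_hz = 10, sampling_hz, n_taps = 51) {
  taps <- fir_lowpass_taps(cutoff_hz, sampling_hz, n_taps)
  n <- length(x)
  if (n <= n_taps) {
    stop("signal length (", n, ") must exceed the filter length (",
         n_taps, ")", call. = FALSE)
  }
  d <- (n_taps - 1L) / 2L
  # reflect both ends so the centred convolution is defined everywhere
  xp <- c(rev(x[seq(2, d + 1)]), x, rev(x)[seq(2, d + 1)])
  y <- stats::filter(xp, taps, method = "convolution", sides = 2)
  as.numeric(y[(d + 1):(d + n)])
}

#' @rdname fir_lowpass
#' @return `fir_lowpass_taps()` returns the numeric tap vector, normalized
#'   to unit DC gain.
#' @export
fir_lowpass_taps <- function(cutoff_hz = 10, sampling_hz, n_taps = 51) {
  if (cutoff_hz >= sampling_hz / 2) {
    stop("cut-off (", cutoff_hz, " Hz) must be below the Nyquist frequency (",
         sampling_hz / 2, " Hz)", call. = FALSE)
  }
  if (n_taps %% 2 == 0) stop("n_taps must be odd", call. = FALSE)
  taps <- signal::fir1(n_taps - 1L, cutoff_hz / (sampling_hz / 2), type = "low")
  as.numeric(taps) / sum(taps)
}

#' Apply the FIR low-pass to every channel of every window
#'
#' @param dataset A [har_dataset].
#' @inheritParams fir_lowpass
#' @return The filtered [har_dataset].
#' @export
filter_dataset <- function(dataset, cutoff_hz = 10, sampling_hz = 50,
                           n_taps = 51) {
  stopifnot(inherits(dataset, "har_dataset"))
  d <- dim(dataset$samples)
  for (w in seq_len(d[1])) {
    for (ch in seq_len(d[3])) {
      dataset$samples[w, , ch] <-
        fir_lowpass(dataset$samples[w, , ch], cutoff_hz, sampling_hz, n_taps)
    }
  }
  dataset
}

#' Sliding-window segmentation of a continuous multi-channel series
#'
#' Cuts a continuous recording of one activity into fixed-duration windows
#' — the classification unit. The default window is 2.56 s, which at 50 Hz
#' gives 128 samples; consecutive windows overlap by 50% unless configured
#' otherwise. The trailing partial window is discarded.
#'
#' @param xyz Numeric matrix `[channels x n_samples]` (or a vector for one
#'   channel).
#' @param window_seconds Window duration in seconds (default 2.56).
#' @param sampling_hz Sampling rate in Hz.
#' @param overlap_fraction Fractional overlap between consecutive windows,
#'   in `[0, 1)`; default 0.5.
#' @param window_samples Window length in samples; derived as
#'   `round(window_seconds * sampling_hz)` when not given.
#' @return Numeric array `[n_windows, window_samples, channels]`; zero
#'   windows (with a warning) when the series is shorter than one window.
#' @examples
#' segment_window_samples(2.56, 50)  # 128
#' @export
segment_stream <- function(xyz, window_seconds = 2.56, sampling_hz,
                           overlap_fraction = 0.5, window_samples = NULL) {
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (is.null(window_samples)) {
    window_samples <- segment_window_samples(window_seconds, sampling_hz)
  }
  if (window_samples < 2) stop("window_samples must be at least 2", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must lie in [0, 1)", call. = FALSE)
  }
  stride <- max(1L, as.integer(round(window_samples * (1 - overlap_fraction))))
  n <- ncol(xyz)
  if (n < window_samples) {
    warning("series of ", n, " samples is shorter than one window (",
            window_samples, "); returning zero windows", call. = FALSE)
    return(array(0, dim = c(0, window_samples, nrow(xyz))))
  }
  n_out <- (n - window_samples) %/% stride + 1L
  out <- array(0, dim = c(n_out, window_samples, nrow(xyz)))
  for (w in seq_len(n_out)) {
    start <- (w - 1L) * stride + 1L
    out[w, , ] <- t(xyz[, start:(start + window_samples - 1L), drop = FALSE])
  }
  out
}

#' @rdname segment_stream
#' @export
segment_window_samples <- function(window_seconds = 2.56, sampling_hz) {
  n <- as.integer(round(window_seconds * sampling_hz))
  if (n < 2) stop("window shorter than 2 samples", call. = FALSE)
  n
}

#' Segment a tibble of sensor streams into a dataset
#'
#' Applies [segment_stream()] to each row of a stream tibble (as returned
#' by [read_wisdm()]) and stacks the results into a [har_dataset], each
#' window inheriting its stream's activity label and user id.
#'
#' @param streams Tibble with `user_id`, `activity` and `xyz` columns.
#' @param vocabulary Vocabulary the activity names belong to.
#' @inheritParams segment_stream
#' @return A [har_dataset]; streams shorter than one window contribute no
#'   windows.
#' @export
segment_streams <- function(streams, window_seconds = 2.56, sampling_hz = 20,
                            overlap_fraction = 0.5, window_samples = NULL,
                            vocabulary = "wisdm") {
  if (is.null(window_samples)) {
    window_samples <- segment_window_samples(window_seconds, sampling_hz)
  }
  pieces <- list()
  labels <- integer(); subjects <- integer()
  for (i in seq_len(nrow(streams))) {
    if (ncol(streams$xyz[[i]]) < window_samples) next
    win <- segment_stream(streams$xyz[[i]], window_seconds, sampling_hz,
                          overlap_fraction, window_samples)
    pieces[[length(pieces) + 1L]] <- win
    labels <- c(labels, rep(label_index(streams$activity[i], vocabulary),
                            dim(win)[1]))
    subjects <- c(subjects, rep(streams$user_id[i], dim(win)[1]))
  }
  n_ch <- if (length(pieces)) dim(pieces[[1]])[3] else 3L
  total <- sum(vapply(pieces, function(p) dim(p)[1], 0L))
  samples <- array(0, dim = c(total, window_samples, n_ch))
  at <- 0L
  for (p in pieces) {
    samples[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  har_dataset(samples, labels, subjects, vocabulary = vocabulary)
}

#' Per-channel standardization
#'
#' Centers and scales each channel to zero mean and unit standard deviation.
#' When `stats` is omitted they are estimated from the dataset (training
#' time); passing previously fitted stats applies them unchanged (test
#' time), so no information leaks from test data into the scaling. A
#' zero-variance channel keeps scale 1 with a warning rather than dividing
#' by zero.
#'
#' @param dataset A [har_dataset].
#' @param stats Optional tibble from a previous call, with columns
#'   `channel`, `mean`, `sd`.
#' @return List with elements `dataset` (standardized) and `stats` (the
#'   tibble actually applied).
#' @export
standardize <- function(dataset, stats = NULL) {
  stopifnot(inherits(dataset, "har_dataset"))
  n_ch <- dim(dataset$samples)[3]
  if (is.null(stats)) {
    mu <- vapply(seq_len(n_ch), function(ch) mean(dataset$samples[, , ch]), 0)
    sdv <- vapply(seq_len(n_ch), function(ch) stats::sd(dataset$samples[, , ch]), 0)
    if (any(sdv == 0 | is.na(sdv))) {
      warning("zero-variance channel(s): scale kept at 1", call. = FALSE)
      sdv[sdv == 0 | is.na(sdv)] <- 1
    }
    stats <- tibble::tibble(channel = seq_len(n_ch), mean = mu, sd = sdv)
  }
  if (nrow(stats) != n_ch) {
    stop("stats must cover all ", n_ch, " channels", call. = FALSE)
  }
  for (ch in seq_len(n_ch)) {
    dataset$samples[, , ch] <-
      (dataset$samples[, , ch] - stats$mean[ch]) / stats$sd[ch]
  }
  list(dataset = dataset, stats = stats)
}

#' Invert a standardization
#' @param dataset A standardized [har_dataset].
#' @param stats The stats tibble returned by [standardize()].
#' @return The de-standardized [har_dataset].
#' @export
unstandardize <- function(dataset, stats) {
  for (ch in seq_len(dim(dataset$samples)[3])) {
    dataset$samples[, , ch] <-
      dataset$samples[, , ch] * stats$sd[ch] + stats$mean[ch]
  }
  dataset
}
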