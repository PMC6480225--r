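#' Construct a windowed inertial dataset
#'
#' The atomic classification unit is a fixed-length multi-channel sensor
#' window: by default 128 samples (2.56 s at 50 Hz) of 6 channels —
#' tri-axial acceleration in g plus tri-axial angular velocity in rad/s.
#' A `har_dataset` holds a batch of such windows as a dense numeric array
#' `[n_windows, window_length, n_channels]` together with 0-based class
#' labels, subject identifiers, and the vocabulary the labels refer to.
#'
#' @param samples Numeric array `[n, length, channels]`, or a single window
#'   as a `[length, channels]` matrix.
#' @param labels Integer vector of 0-based class indices, length `n`.
#' @param subjects Integer vector of subject ids, length `n` (recycled if
#'   scalar).
#' @param vocabulary `"uci"` or `"wisdm"`.
#' @param split_tag One of `"train"`, `"test"`, `"all"`.
#' @param channel_names Optional character vector naming the channels.
#' @return An object of class `har_dataset`.
#' @export
har_dataset <- function(samples, labels, subjects = 0L,
                        vocabulary = "uci", split_tag = "all",
                        channel_names = NULL) {
  if (is.matrix(samples)) {
    samples <- array(samples, dim = c(1L, nrow(samples), ncol(samples)))
  }
  stopifnot(is.array(samples), length(dim(samples)) == 3L)
  if (anyNA(samples)) stop("windows must not contain missing values", call. = FALSE)
  n <- dim(samples)[1]
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels length must match window count", call. = FALSE)
  n_classes <- nrow(activity_vocabulary(vocabulary))
  if (n > 0 && (min(labels) < 0L || max(labels) >= n_classes)) {
    stop("labels must be 0-based indices below ", n_classes, call. = FALSE)
  }
  subjects <- as.integer(rep_len(subjects, n))
  split_tag <- match.arg(split_tag, c("train", "test", "all"))
  if (!is.null(channel_names) && length(channel_names) != dim(samples)[3]) {
    stop("channel_names length must equal the channel count", call. = FALSE)
  }
  structure(
    list(samples = samples, labels = labels, subjects = subjects,
         vocabulary = vocabulary, split_tag = split_tag,
         channel_names = channel_names),
    class = "har_dataset"
  )
}

#' Number of windows in a dataset
#' @param dataset A [har_dataset].
#' @return Integer count.
#' @export
n_windows <- function(dataset) dim(dataset$samples)[1]

#' @export
dim.har_dataset <- function(x) dim(x$samples)

#' Subset a dataset by window index
#' @param x A [har_dataset].
#' @param i Integer or logical index over windows.
#' @param ... Unused.
#' @export
`[.har_dataset` <- function(x, i, ...) {
  har_dataset(x$samples[i, , , drop = FALSE], x$labels[i], x$subjects[i],
              vocabulary = x$vocabulary, split_tag = x$split_tag,
              channel_names = x$channel_names)
}

#' Per-class window counts
#'
#' @param dataset A [har_dataset].
#' @return Tibble with one row per vocabulary class: `name`, `index`, `n`.
#'   Classes absent from the dataset appear with `n = 0`, so the counts
#'   always sum to `n_windows(dataset)`.
#' @export
window_counts <- function(dataset) {
  vocab <- activity_vocabulary(dataset$vocabulary)
  counts <- tabulate(dataset$labels + 1L, nbins = nrow(vocab))
  dplyr::mutate(vocab, n = as.integer(counts))
}

#' Activity names of the windows in a dataset
#' @param dataset A [har_dataset].
#' @return Character vector, one name per window.
#' @export
window_labels <- function(dataset) {
  vocab_names(dataset$vocabulary)[dataset$labels + 1L]
}

#' Bind two datasets sharing geometry and vocabulary
#' @keywords internal
#' @noRd
bind_datasets <- function(a, b) {
  stopifnot(identical(a$vocabulary, b$vocabulary),
            identical(dim(a$samples)[-1], dim(b$samples)[-1]))
  samples <- array(0, dim = c(n_windows(a) + n_windows(b), dim(a$samples)[2],
                              dim(a$samples)[3]))
  if (n_windows(a) > 0) samples[seq_len(n_windows(a)), , ] <- a$samples
  if (n_windows(b) > 0) samples[n_windows(a) + seq_len(n_windows(b)), , ] <- b$samples
  har_dataset(samples, c(a$labels, b$labels), c(a$subjects, b$subjects),
              vocabulary = a$vocabulary, split_tag = "all",
              channel_names = a$channel_names)
}

#' @export
print.har_dataset <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<har_dataset> %d windows x %d samples x %d channels (%s, %s)\n",
              d[1], d[2], d[3], x$vocabulary, x$split_tag))
  cat(sprintf("  subjects: %d distinct\n", length(unique(x$subjects))))
  counts <- window_counts(x)
  cat("  per class: ",
      paste(sprintf("%s=%d", counts$name, counts$n), collapse = ", "), "\n")
  invisible(x)
}

#' One-row-per-window view of a dataset
#'
#' @param x A [har_dataset].
#' @param ... Unused.
#' @return Tibble with `window`, `activity`, `index`, `subject` columns.
#' @method as_tibble har_dataset
#' @export
as_tibble.har_dataset <- function(x, ...) {
  tibble::tibble(
    window = seq_len(n_windows(x)),
    activity = window_labels(x),
    index = x$labels,
    subject = x$subjects
  )
}
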