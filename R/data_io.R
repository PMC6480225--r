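#' Read the UCI HAR raw inertial-signal layout
#'
#' The UCI smartphone HAR benchmark ships, per split, nine whitespace-
#' delimited text matrices under `Inertial Signals/` (one 128-sample window
#' per row) plus `y_<split>.txt` (activity codes 1-6) and
#' `subject_<split>.txt` (volunteer ids). Six of the nine signal groups form
#' the network input: a tri-axial accelerometer variant plus the tri-axial
#' body gyroscope. The benchmark provides both the total acceleration and a
#' gravity-removed body acceleration; `channel_set` selects which variant
#' feeds the accelerometer channels.
#'
#' @param root_dir Dataset root containing `train/` and/or `test/`.
#' @param split `"train"` or `"test"`.
#' @param channel_set `"total_acc"` (default) or `"body_acc"`.
#' @return A [har_dataset] with one 128 x 6 window per label row, labels
#'   converted to 0-based indices, and subject ids attached.
#' @export
read_uci_har <- function(root_dir, split = c("train", "test"),
                         channel_set = c("total_acc", "body_acc")) {
  split <- match.arg(split)
  channel_set <- match.arg(channel_set)
  split_dir <- file.path(root_dir, split)
  signal_dir <- file.path(split_dir, "Inertial Signals")
  groups <- c(paste0(channel_set, "_", c("x", "y", "z")),
              paste0("body_gyro_", c("x", "y", "z")))
  signal_files <- file.path(signal_dir, paste0(groups, "_", split, ".txt"))
  label_file <- file.path(split_dir, paste0("y_", split, ".txt"))
  subject_file <- file.path(split_dir, paste0("subject_", split, ".txt"))

  for (f in c(signal_files, label_file, subject_file)) {
    if (!file.exists(f)) {
      stop("UCI HAR ingestion error: missing file '", f, "'", call. = FALSE)
    }
  }

  labels_raw <- scan(label_file, what = integer(), quiet = TRUE)
  subjects <- scan(subject_file, what = integer(), quiet = TRUE)
  n <- length(labels_raw)
  if (length(subjects) != n) {
    stop("UCI HAR consistency error: ", n, " labels but ",
         length(subjects), " subject rows", call. = FALSE)
  }
  if (n > 0 && (min(labels_raw) < 1L || max(labels_raw) > 6L)) {
    stop("UCI HAR labels must be activity codes 1-6", call. = FALSE)
  }

  channel_mats <- lapply(signal_files, function(f) {
    vals <- scan(f, what = double(), quiet = TRUE)
    if (n == 0 && length(vals) == 0) {
      return(matrix(numeric(0), nrow = 0, ncol = 128))
    }
    if (length(vals) %% n != 0) {
      stop("UCI HAR consistency error: '", basename(f), "' has ",
           length(vals), " values, not a multiple of ", n, " windows",
           call. = FALSE)
    }
    matrix(vals, nrow = n, byrow = TRUE)
  })
  window_len <- if (n > 0) ncol(channel_mats[[1]]) else 128L
  if (any(vapply(channel_mats, ncol, 0L) != window_len)) {
    stop("UCI HAR consistency error: signal files disagree on window length",
         call. = FALSE)
  }

  samples <- array(0, dim = c(n, window_len, 6L))
  for (ch in seq_along(channel_mats)) samples[, , ch] <- channel_mats[[ch]]
  har_dataset(samples, labels_raw - 1L, subjects,
              vocabulary = "uci", split_tag = split, channel_names = groups)
}

#' Parse a WISDM raw accelerometer log
#'
#' WISDM records lines of the form `user,activity,timestamp,x,y,z;` sampled
#' at 20 Hz; the public file contains occasional glitches (blank lines,
#' truncated records, several records glued on one line). Malformed records
#' are skipped with a warning and counted rather than aborting the read;
#' activity names outside the WISDM vocabulary abort, since they indicate
#' the wrong file rather than a glitch.
#'
#' @param path Path to the raw text log.
#' @return A tibble of sensor streams — maximal contiguous runs of one
#'   (user, activity) pair — with columns `user_id`, `activity`,
#'   `n_samples`, and list-columns `timestamps` (numeric nanoseconds) and
#'   `xyz` (a `3 x n_samples` matrix per stream). The number of skipped
#'   records is attached as attribute `skipped`.
#' @export
read_wisdm <- function(path) {
  if (!file.exists(path)) {
    stop("WISDM ingestion error: missing file '", path, "'", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  # one physical line may carry several ';'-terminated records
  records <- unlist(strsplit(lines, ";", fixed = TRUE), use.names = FALSE)
  records <- trimws(records)
  records <- records[nzchar(records)]

  empty <- tibble::tibble(user_id = integer(), activity = character(),
                          n_samples = integer(), timestamps = list(),
                          xyz = list())
  if (length(records) == 0) {
    attr(empty, "skipped") <- 0L
    return(empty)
  }

  fields <- strsplit(records, ",", fixed = TRUE)
  ok <- lengths(fields) == 6L
  parsed <- matrix(NA_character_, nrow = length(records), ncol = 6)
  parsed[ok, ] <- matrix(unlist(fields[ok]), ncol = 6, byrow = TRUE)
  user <- suppressWarnings(as.integer(parsed[, 1]))
  ts <- suppressWarnings(as.numeric(parsed[, 3]))
  x <- suppressWarnings(as.numeric(parsed[, 4]))
  y <- suppressWarnings(as.numeric(parsed[, 5]))
  z <- suppressWarnings(as.numeric(parsed[, 6]))
  numeric_ok <- !is.na(user) & !is.na(ts) & !is.na(x) & !is.na(y) & !is.na(z)
  keep <- ok & numeric_ok
  skipped <- sum(!keep)
  if (skipped > 0) {
    warning(skipped, " malformed WISDM record(s) skipped", call. = FALSE)
  }
  if (!any(keep)) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }

  activity_raw <- tolower(parsed[keep, 2])
  vocab <- vocab_names("wisdm")
  if (!all(activity_raw %in% vocab)) {
    bad <- unique(parsed[keep, 2][!(activity_raw %in% vocab)])
    stop("activity name(s) outside the WISDM vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  user <- user[keep]; ts <- ts[keep]
  xyz_all <- rbind(x[keep], y[keep], z[keep])
  run_id <- cumsum(c(TRUE, user[-1] != user[-length(user)] |
                       activity_raw[-1] != activity_raw[-length(activity_raw)]))
  idx_by_run <- split(seq_along(run_id), run_id)
  out <- tibble::tibble(
    user_id = unname(vapply(idx_by_run, function(i) user[i[1]], 0L)),
    activity = unname(vapply(idx_by_run, function(i) activity_raw[i[1]], "")),
    n_samples = unname(lengths(idx_by_run)),
    timestamps = unname(lapply(idx_by_run, function(i) ts[i])),
    xyz = unname(lapply(idx_by_run, function(i) xyz_all[, i, drop = FALSE]))
  )
  attr(out, "skipped") <- skipped
  out
}

#' Write a dataset as a miniature UCI HAR directory
#'
#' Serializes a UCI-vocabulary dataset into the exact on-disk layout
#' [read_uci_har()] expects (per-split `Inertial Signals/` matrices, label
#' and subject files), so synthetic fixtures round-trip through the reader.
#' Values are written with 8 significant digits, so samples survive the
#' round trip to well within 1e-6 absolute.
#'
#' @param dataset A [har_dataset] with UCI vocabulary and 6 channels.
#' @param root_dir Directory to create the layout under.
#' @param split Split subdirectory to write (`"train"` or `"test"`).
#' @param channel_set Accelerometer variant name used in the file names.
#' @return `root_dir`, invisibly.
#' @export
write_fixture_uci <- function(dataset, root_dir, split = "train",
                              channel_set = "total_acc") {
  stopifnot(inherits(dataset, "har_dataset"))
  if (!identical(dataset$vocabulary, "uci")) {
    stop("write_fixture_uci requires the UCI vocabulary", call. = FALSE)
  }
  if (dim(dataset$samples)[3] != 6L) {
    stop("write_fixture_uci requires 6-channel windows", call. = FALSE)
  }
  split <- match.arg(split, c("train", "test"))
  signal_dir <- file.path(root_dir, split, "Inertial Signals")
  dir.create(signal_dir, recursive = TRUE, showWarnings = FALSE)
  groups <- c(paste0(channel_set, "_", c("x", "y", "z")),
              paste0("body_gyro_", c("x", "y", "z")))
  for (ch in seq_along(groups)) {
    mat <- dataset$samples[, , ch, drop = TRUE]
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = n_windows(dataset))
    lines <- apply(mat, 1, function(row) {
      paste(sprintf("% .8e", row), collapse = " ")
    })
    writeLines(lines, file.path(signal_dir, paste0(groups[ch], "_", split, ".txt")))
  }
  writeLines(as.character(dataset$labels + 1L),
             file.path(root_dir, split, paste0("y_", split, ".txt")))
  writeLines(as.character(dataset$subjects),
             file.path(root_dir, split, paste0("subject_", split, ".txt")))
  invisible(root_dir)
}

#' Write streams or a dataset in the WISDM raw line format
#'
#' Emits `user,activity,timestamp,x,y,z;` lines from the first three
#' channels of each window at the given sampling rate. Useful for
#' generating WISDM-format fixtures from synthetic datasets.
#'
#' @param dataset A [har_dataset] with the WISDM vocabulary.
#' @param path Output file path.
#' @param sampling_hz Sampling rate used to synthesize timestamps.
#' @return `path`, invisibly.
#' @export
write_fixture_wisdm <- function(dataset, path, sampling_hz = 20) {
  stopifnot(inherits(dataset, "har_dataset"))
  if (!identical(dataset$vocabulary, "wisdm")) {
    stop("write_fixture_wisdm requires the WISDM vocabulary", call. = FALSE)
  }
  step_ns <- round(1e9 / sampling_hz)
  vocab <- vocab_names("wisdm")
  # capitalized names as in the raw file
  pretty <- c(walking = "Walking", jogging = "Jogging", upstairs = "Upstairs",
              downstairs = "Downstairs", sitting = "Sitting",
              standing = "Standing")
  con <- file(path, "w"); on.exit(close(con))
  t0 <- 0
  for (w in seq_len(n_windows(dataset))) {
    act <- pretty[[vocab[dataset$labels[w] + 1L]]]
    n <- dim(dataset$samples)[2]
    ts <- t0 + step_ns * (seq_len(n) - 1)
    lines <- sprintf("%d,%s,%.0f,%.4f,%.4f,%.4f;",
                     dataset$subjects[w], act, ts,
                     dataset$samples[w, , 1], dataset$samples[w, , 2],
                     dataset$samples[w, , 3])
    writeLines(lines, con)
    t0 <- ts[n] + step_ns
  }
  invisible(path)
}
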