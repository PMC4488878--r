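#' Construct a raw EEG epoch
#'
#' A channels x samples slice of EEG around one cursor action, plus the
#' metadata feature extraction needs.
#'
#' @param samples Numeric channels x time matrix.
#' @param sampling_rate Sampling rate in Hz.
#' @param t0_index 1-based column index of the action onset (time 0).
#' @param channel_names Channel names, one per row of `samples`.
#' @return Object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(samples, sampling_rate, t0_index,
                      channel_names = rownames(samples)) {
  samples <- as.matrix(samples)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(samples)))
  stopifnot(sampling_rate > 0,
            t0_index >= 1, t0_index <= ncol(samples),
            length(channel_names) == nrow(samples))
  rownames(samples) <- channel_names
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 t0_index = as.integer(t0_index),
                 channel_names = channel_names),
            class = "eeg_epoch")
}

#' Feature extraction configuration
#'
#' Defaults reproduce the package's reference recipe: channels Fz, FCz, Cz,
#' window 200 to 800 ms after action onset, temporal downsampling by 8 -- at a
#' 256 Hz sampling rate this yields 19 samples per channel and a 57-dimensional
#' feature vector.
#'
#' @param window_ms Length-2 numeric, window start/end in ms relative to onset.
#' @param downsample Integer decimation factor (keep every k-th sample).
#' @param channels Channel names, concatenated in this order.
#' @param bandpass Optional `c(low_Hz, high_Hz)` zero-phase band-pass applied
#'   before windowing (epochs are normally already filtered at acquisition).
#' @return Object of class `feature_config`.
#' @export
feature_config <- function(window_ms = c(200, 800), downsample = 8L,
                           channels = c("Fz", "FCz", "Cz"), bandpass = NULL) {
  stopifnot(length(window_ms) == 2L, window_ms[2L] > window_ms[1L],
            downsample >= 1L)
  structure(list(window_ms = as.numeric(window_ms),
                 downsample = as.integer(downsample),
                 channels = channels, bandpass = bandpass),
            class = "feature_config")
}

# Sample offsets (relative to onset, 0-based) selected by a config at a given
# sampling rate. Convention, fixed by the requirement that the reference
# recipe yields exactly 19 samples/channel at 256 Hz: half-open sample window
# [ceiling(fs * t_start), floor(fs * t_end)), keeping every `downsample`-th
# sample starting at the window's first sample.
.window_offsets <- function(cfg, sampling_rate) {
  first <- ceiling(sampling_rate * cfg$window_ms[1L] / 1000)
  last <- floor(sampling_rate * cfg$window_ms[2L] / 1000) - 1
  if (last < first)
    stop("empty feature window at sampling rate ", sampling_rate, call. = FALSE)
  seq(first, last, by = cfg$downsample)
}

#' Number of features produced by a configuration
#'
#' Depends only on the configuration, the sampling rate and the channel
#' count -- never on epoch content.
#'
#' @param cfg A [feature_config()].
#' @param sampling_rate Sampling rate in Hz.
#' @return Integer dimensionality d.
#' @export
n_features <- function(cfg, sampling_rate) {
  length(.window_offsets(cfg, sampling_rate)) * length(cfg$channels)
}

#' Extract an ErrP feature vector from an epoch
#'
#' Per configured channel, selects the configured post-onset window, decimates
#' it, and concatenates channels in configuration order. Linear in the epoch
#' samples.
#'
#' @param epoch An [eeg_epoch()].
#' @param cfg A [feature_config()].
#' @return Numeric feature vector of length [n_features()].
#' @export
extract_features <- function(epoch, cfg = feature_config()) {
  missing <- setdiff(cfg$channels, epoch$channel_names)
  if (length(missing))
    stop("epoch is missing channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  samples <- epoch$samples
  if (!is.null(cfg$bandpass))
    samples <- t(apply(samples, 1L, .bandpass,
                       sampling_rate = epoch$sampling_rate,
                       band = cfg$bandpass))
  off <- .window_offsets(cfg, epoch$sampling_rate)
  cols <- epoch$t0_index + off
  if (min(cols) < 1L || max(cols) > ncol(samples))
    stop("epoch too short for the configured window (needs samples ",
         min(cols), "..", max(cols), ", has ", ncol(samples), ")",
         call. = FALSE)
  as.numeric(t(samples[cfg$channels, cols, drop = FALSE]))
}

# Zero-phase Butterworth band-pass (order 4, applied forward and backward).
.bandpass <- function(x, sampling_rate, band, order = 4L) {
  ny <- sampling_rate / 2
  bf <- signal::butter(order, band / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Write / read feature records as delimited text
#'
#' One feature vector per row, comma-separated at 17 significant digits (so a
#' write/read round trip is bit exact), with a header and an optional integer
#' label column (1 = correct, 2 = error).
#'
#' @param x Numeric matrix of feature rows.
#' @param labels Optional integer labels (1/2), one per row.
#' @param path File path (`.csv`), or for `read_features` optionally a Feather
#'   file written by [write_features()] with `format = "arrow"`.
#' @param format `"csv"` (default) or `"arrow"` (columnar binary via the
#'   arrow package, for large sets).
#' @return `read_features()` returns `list(features, labels)` (`labels` NULL
#'   when absent).
#' @export
write_features <- function(x, labels = NULL, path, format = c("csv", "arrow")) {
  format <- match.arg(format)
  x <- as.matrix(x)
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(x))
    df$label <- as.integer(labels)
  }
  if (format == "arrow") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is required for format = 'arrow'", call. = FALSE)
    arrow::write_feather(df, path)
  } else {
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path, format = c("auto", "csv", "arrow")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(feather|arrow)$", path)) "arrow" else "csv"
  if (format == "arrow") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is required for format = 'arrow'", call. = FALSE)
    df <- as.data.frame(arrow::read_feather(path))
  } else {
    df <- tryCatch(
      utils::read.csv(path, header = TRUE),
      warning = function(w) stop("malformed feature file '", path, "': ",
                                 conditionMessage(w), call. = FALSE),
      error = function(e) stop("malformed feature file '", path, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.integer(df$label)
    df$label <- NULL
  }
  feat <- as.matrix(df)
  if (!is.numeric(feat))
    suppressWarnings(storage.mode(feat) <- "numeric")
  if (anyNA(feat))
    stop("malformed feature file '", path, "': non-numeric or ragged rows",
         call. = FALSE)
  dimnames(feat) <- NULL
  list(features = feat, labels = labels)
}

#' Write / read raw epochs as delimited text
#'
#' Tall CSV with columns `epoch, channel, sample, value` (`sample` is the
#' 1-based column index) preceded by comment headers (`# sampling_rate=`,
#' `# t0_index=`) holding the shared metadata.
#'
#' @param epochs List of [eeg_epoch()] objects sharing sampling rate, onset
#'   index and channel set.
#' @param path File path.
#' @return `read_epochs()` returns a list of [eeg_epoch()].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(length(epochs) >= 1L)
  e1 <- epochs[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# sampling_rate=", format(e1$sampling_rate, digits = 17)),
               paste0("# t0_index=", e1$t0_index),
               "epoch,channel,sample,value"), con)
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    for (ch in ep$channel_names) {
      vals <- format(ep$samples[ch, ], digits = 17, trim = TRUE)
      writeLines(paste(i, ch, seq_along(vals), vals, sep = ","), con)
    }
  }
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  hdr <- readLines(path, n = 2L)
  meta <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, "="))]
    if (!length(ln)) stop("epoch file '", path, "' lacks '", key, "' header",
                          call. = FALSE)
    as.numeric(sub(paste0("# ", key, "="), "", ln))
  }
  fs <- meta("sampling_rate")
  t0 <- meta("t0_index")
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("epoch", "channel", "sample", "value")
  if (!all(need %in% names(df)))
    stop("epoch file '", path, "' lacks columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  lapply(split(df, df$epoch), function(d) {
    chans <- unique(d$channel)
    m <- do.call(rbind, lapply(chans, function(ch) {
      dd <- d[d$channel == ch, ]
      dd$value[order(dd$sample)]
    }))
    rownames(m) <- chans
    eeg_epoch(m, fs, t0, chans)
  })
}
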