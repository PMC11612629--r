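#' Construct a single-channel EEG record
#'
#' The basic data container of the package: one channel of real-valued
#' samples together with its sampling rate, an optional class label, and
#' free-text provenance.
#'
#' @param samples Numeric vector of samples (conventionally microvolts).
#' @param fs Sampling rate in Hz.
#' @param label One of `"healthy"`, `"interictal"`, `"ictal"` or `NA` for
#'   unlabeled data.
#' @param source_id Free-text provenance (file name, subset letter,
#'   channel name).
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs, label = NA_character_, source_id = "") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("'samples' must be non-empty")
  if (!all(is.finite(samples))) stop("'samples' must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("'fs' must be a positive number")
  if (!is.na(label) && !label %in% c("healthy", "interictal", "ictal")) {
    stop("'label' must be healthy, interictal, ictal or NA")
  }
  structure(list(samples = samples, fs = fs, label = label, source_id = source_id),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d samples @ %.2f Hz, label=%s, source=%s\n",
              length(x$samples), x$fs, x$label, x$source_id))
  invisible(x)
}

#' Read a Bonn-format EEG record
#'
#' Bonn University epilepsy records are plain ASCII, one integer sample per
#' line, 4,097 samples recorded at 173.61 Hz.
#'
#' @param path Path to the text file.
#' @param label Class label to attach (`"healthy"`, `"interictal"`,
#'   `"ictal"`, or `NA`).
#' @param fs Sampling rate; defaults to the Bonn acquisition rate.
#' @return An [eeg_record].
#' @export
read_bonn_record <- function(path, label = NA_character_, fs = 173.61) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("non-numeric value at line %d of %s: '%s'", bad, path, lines[bad]))
  }
  eeg_record(vals, fs = fs, label = label, source_id = basename(path))
}

#' Write a record in the Bonn ASCII dialect
#'
#' One sample per line; used by the synthetic-data tools so generated
#' records flow through the identical reader path as real data.
#'
#' @param record An [eeg_record].
#' @param path Output file path.
#' @export
write_bonn_record <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  writeLines(format(record$samples, scientific = FALSE, trim = TRUE), path)
  invisible(path)
}

#' Filter specification for EEG preprocessing
#'
#' Defaults follow routine clinical preprocessing: a fourth-order
#' Butterworth bandpass at 0.5--70 Hz followed by a 50 Hz mains notch.
#'
#' @param band_low,band_high Bandpass edges in Hz.
#' @param order Butterworth order.
#' @param notch_freq Notch centre frequency in Hz (`NA` disables the notch).
#' @param notch_q Notch quality factor (centre frequency / -3 dB width).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(band_low = 0.5, band_high = 70, order = 4,
                        notch_freq = 50, notch_q = 30) {
  if (band_low <= 0 || band_high <= band_low) stop("need 0 < band_low < band_high")
  if (order < 1) stop("'order' must be >= 1")
  structure(list(band_low = band_low, band_high = band_high, order = order,
                 notch_freq = notch_freq, notch_q = notch_q),
            class = "filter_spec")
}

# Second-order IIR notch (Audio-EQ biquad): centre w0, -3 dB width w0/Q.
notch_coefficients <- function(freq, fs, q) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Apply bandpass and notch filters to a record
#'
#' The Butterworth bandpass is applied forward-backward (zero phase) so
#' downstream features are not phase-distorted, followed by the mains
#' notch, also zero-phase. Output has the same length and sampling rate.
#'
#' @param record An [eeg_record].
#' @param spec A [filter_spec].
#' @param clamp_band If `TRUE` (default), a `band_high` at or above the
#'   Nyquist frequency is clamped to `0.99 * fs / 2` so one specification
#'   can serve records at different rates; if `FALSE` this is an error.
#' @return A filtered [eeg_record].
#' @export
apply_filters <- function(record, spec = filter_spec(), clamp_band = TRUE) {
  stopifnot(inherits(record, "eeg_record"), inherits(spec, "filter_spec"))
  nyq <- record$fs / 2
  band_high <- spec$band_high
  if (band_high >= nyq) {
    if (!clamp_band) stop("band_high (", band_high, " Hz) must be below Nyquist (", nyq, " Hz)")
    band_high <- 0.99 * nyq
  }
  bf <- signal::butter(spec$order, c(spec$band_low, band_high) / nyq, type = "pass")
  y <- signal::filtfilt(bf, record$samples)
  if (!is.na(spec$notch_freq) && spec$notch_freq < nyq) {
    nc <- notch_coefficients(spec$notch_freq, record$fs, spec$notch_q)
    y <- signal::filtfilt(signal::Arma(b = nc$b, a = nc$a), y)
  }
  eeg_record(y, fs = record$fs, label = record$label,
             source_id = record$source_id)
}

#' Cut a record into fixed-length overlapping windows
#'
#' Windows of `window_len` samples start at multiples of the stride
#' `window_len - overlap`; a trailing partial window is discarded. Each
#' segment inherits the record's label.
#'
#' @param record An [eeg_record].
#' @param window_len Window length in samples.
#' @param overlap Number of samples shared by consecutive windows.
#' @return A `segment_set`: list with `segments` (matrix, one row per
#'   window), `labels`, `window_len`, `overlap`, `fs`.
#' @export
segment_record <- function(record, window_len = 1024, overlap = 64) {
  stopifnot(inherits(record, "eeg_record"))
  if (overlap < 0 || overlap >= window_len) stop("need 0 <= overlap < window_len")
  n <- length(record$samples)
  stride <- window_len - overlap
  if (window_len > n) {
    warning("record shorter than window: returning empty segment set")
    starts <- integer(0)
  } else {
    n_seg <- floor((n - window_len) / stride) + 1L
    starts <- (seq_len(n_seg) - 1L) * stride
  }
  segs <- matrix(0, nrow = length(starts), ncol = window_len)
  for (i in seq_along(starts)) {
    segs[i, ] <- record$samples[(starts[i] + 1):(starts[i] + window_len)]
  }
  structure(list(segments = segs,
                 labels = rep(record$label, length(starts)),
                 window_len = window_len, overlap = overlap, fs = record$fs),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments x %d samples @ %.2f Hz (overlap %d)\n",
              nrow(x$segments), x$window_len, x$fs, x$overlap))
  invisible(x)
}

#' Combine several segment sets
#'
#' @param ... `segment_set` objects with identical window parameters.
#' @return A single `segment_set`.
#' @export
bind_segment_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "segment_set")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) >= 1L)
  wl <- unique(vapply(sets, `[[`, numeric(1), "window_len"))
  fs <- unique(vapply(sets, `[[`, numeric(1), "fs"))
  ov <- unique(vapply(sets, `[[`, numeric(1), "overlap"))
  if (length(wl) != 1L || length(fs) != 1L) stop("segment sets are not compatible")
  structure(list(segments = do.call(rbind, lapply(sets, `[[`, "segments")),
                 labels = unlist(lapply(sets, `[[`, "labels")),
                 window_len = wl, overlap = ov[1], fs = fs),
            class = "segment_set")
}

#' Stratified train/validation/test split of segments
#'
#' Within each label, segments are shuffled with the given seed and
#' allocated by floor counts; remainders go to train, then validation,
#' then test. The three outputs are disjoint and their union is the input.
#'
#' @param segset A `segment_set`.
#' @param fractions Numeric length-3 vector `(train, val, test)` summing
#'   to 1; the conventional protocol is 90/5/5.
#' @param seed Integer seed controlling the shuffle.
#' @return Named list `train`, `val`, `test` of `segment_set` objects.
#' @export
split_segments <- function(segset, fractions = c(0.9, 0.05, 0.05), seed = 0L) {
  stopifnot(inherits(segset, "segment_set"))
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("'fractions' must be three positive numbers summing to 1")
  }
  labs <- segset$labels
  counts <- table(labs, useNA = "ifany")
  if (any(counts < 3)) stop("every label needs at least 3 segments to stratify")
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(seed, {
    for (lv in unique(labs)) {
      rows <- which(if (is.na(lv)) is.na(labs) else !is.na(labs) & labs == lv)
      rows <- sample(rows)
      n <- length(rows)
      base <- floor(fractions * n)
      rem <- n - sum(base)
      add <- rep(0L, 3)
      if (rem > 0) add[seq_len(rem)] <- 1L   # remainders: train, val, test
      sizes <- base + add
      cuts <- cumsum(sizes)
      idx$train <- c(idx$train, rows[seq_len(cuts[1])])
      idx$val <- c(idx$val, rows[seq.int(cuts[1] + 1, length.out = sizes[2])])
      idx$test <- c(idx$test, rows[seq.int(cuts[2] + 1, length.out = sizes[3])])
    }
  })
  subset_set <- function(rows) {
    structure(list(segments = segset$segments[rows, , drop = FALSE],
                   labels = segset$labels[rows],
                   window_len = segset$window_len, overlap = segset$overlap,
                   fs = segset$fs),
              class = "segment_set")
  }
  lapply(idx, subset_set)
}

#' Write / read a segment set as a columnar table with a JSON sidecar
#'
#' The segment matrix goes to CSV (one row per segment plus a `label`
#' column); window length, overlap and sampling rate go to `<path>.json`.
#'
#' @param segset A `segment_set`.
#' @param path CSV file path.
#' @return `path`, invisibly (`write_segments`); a `segment_set`
#'   (`read_segments`).
#' @export
write_segments <- function(segset, path) {
  stopifnot(inherits(segset, "segment_set"))
  df <- as.data.frame(segset$segments)
  names(df) <- paste0("s", seq_len(ncol(df)))
  df$label <- segset$labels
  write.csv(df, path, row.names = FALSE)
  meta <- list(window_len = segset$window_len, overlap = segset$overlap, fs = segset$fs)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  labels <- df$label
  df$label <- NULL
  structure(list(segments = as.matrix(df), labels = as.character(labels),
                 window_len = meta$window_len, overlap = meta$overlap,
                 fs = meta$fs),
            class = "segment_set")
}

#' Read seizure annotation intervals from a sidecar file
#'
#' Tab-separated file with columns `record_id`, `start_s`, `end_s`
#' giving annotated seizure intervals in seconds.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `record_id`, `start_s`, `end_s`.
#' @export
read_annotation_intervals <- function(path) {
  df <- read.csv(path, sep = "\t", header = FALSE,
                 col.names = c("record_id", "start_s", "end_s"))
  df$start_s <- as.numeric(df$start_s)
  df$end_s <- as.numeric(df$end_s)
  df
}

#' Label segments from annotated seizure intervals
#'
#' A segment is labelled `"ictal"` when at least half of its samples fall
#' inside an annotated interval, otherwise `background_label`.
#'
#' @param segset A `segment_set` cut from one record.
#' @param intervals Data frame as returned by [read_annotation_intervals],
#'   already filtered to the record in question.
#' @param background_label Label for non-seizure segments.
#' @return The `segment_set` with labels replaced.
#' @export
label_segments <- function(segset, intervals, background_label = "interictal") {
  stopifnot(inherits(segset, "segment_set"))
  stride <- segset$window_len - segset$overlap
  starts <- (seq_len(nrow(segset$segments)) - 1L) * stride
  t0 <- starts / segset$fs
  t1 <- (starts + segset$window_len) / segset$fs
  labs <- rep(background_label, length(t0))
  for (i in seq_along(t0)) {
    covered <- 0
    for (k in seq_len(nrow(intervals))) {
      covered <- covered +
        max(0, min(t1[i], intervals$end_s[k]) - max(t0[i], intervals$start_s[k]))
    }
    if (covered >= (t1[i] - t0[i]) / 2) labs[i] <- "ictal"
  }
  segset$labels <- labs
  segset
}
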