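# Minimal European Data Format (EDF) support: enough of the standard to
# read continuous scalp-EEG recordings such as CHB-MIT (16-bit samples,
# fixed-rate signals) and to write small test files. Annotations (EDF+)
# are not parsed; seizure intervals come from sidecar files instead.

read_edf_header <- function(con) {
  read_str <- function(n) {
    raw <- readBin(con, "raw", n = n)
    trimws(rawToChar(raw))
  }
  version <- read_str(8)
  patient <- read_str(80)
  recording <- read_str(80)
  startdate <- read_str(8)
  starttime <- read_str(8)
  header_bytes <- suppressWarnings(as.integer(read_str(8)))
  reserved <- read_str(44)
  n_records <- suppressWarnings(as.integer(read_str(8)))
  record_dur <- suppressWarnings(as.numeric(read_str(8)))
  ns <- suppressWarnings(as.integer(read_str(4)))
  if (is.na(ns) || ns < 1 || is.na(n_records) || is.na(record_dur)) {
    stop("corrupt EDF header")
  }
  field <- function(width, as = "character") {
    v <- vapply(seq_len(ns), function(i) read_str(width), character(1))
    if (as == "numeric") suppressWarnings(as.numeric(v)) else v
  }
  labels <- field(16)
  transducer <- field(80)
  dim_ <- field(8)
  phys_min <- field(8, "numeric")
  phys_max <- field(8, "numeric")
  dig_min <- field(8, "numeric")
  dig_max <- field(8, "numeric")
  prefilter <- field(80)
  samples_per_record <- field(8, "numeric")
  field(32)  # per-signal reserved
  list(version = version, patient = patient, recording = recording,
       startdate = startdate, starttime = starttime,
       header_bytes = header_bytes, n_records = n_records,
       record_dur = record_dur, ns = ns, labels = labels,
       phys_min = phys_min, phys_max = phys_max,
       dig_min = dig_min, dig_max = dig_max,
       samples_per_record = as.integer(samples_per_record))
}

#' Read channels of an EDF file as EEG records
#'
#' Parses the standard EDF header and 16-bit sample records, converting
#' digital values to physical units with each signal's calibration. One
#' [eeg_record] per selected channel is returned; labels are left `NA`
#' (seizure annotations are attached by the caller, e.g. via
#' [label_segments]).
#'
#' @param path Path to an EDF file.
#' @param channels Character vector of channel labels, or `"all"`.
#' @return List of [eeg_record] objects.
#' @export
read_edf_records <- function(path, channels = "all") {
  if (!file.exists(path)) stop("cannot read file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_edf_header(con)
  sel <- if (identical(channels, "all")) seq_len(hdr$ns) else {
    m <- match(channels, hdr$labels)
    if (anyNA(m)) {
      stop("channel(s) not found: ", paste(channels[is.na(m)], collapse = ", "),
           "; available: ", paste(hdr$labels, collapse = ", "))
    }
    m
  }
  total_per_record <- sum(hdr$samples_per_record)
  data <- readBin(con, "integer", n = hdr$n_records * total_per_record,
                  size = 2, signed = TRUE, endian = "little")
  if (length(data) < hdr$n_records * total_per_record) stop("truncated EDF data section")
  offsets <- c(0, cumsum(hdr$samples_per_record))
  out <- vector("list", length(sel))
  for (k in seq_along(sel)) {
    s <- sel[k]
    nspr <- hdr$samples_per_record[s]
    sig <- numeric(hdr$n_records * nspr)
    for (r in seq_len(hdr$n_records)) {
      from <- (r - 1) * total_per_record + offsets[s] + 1
      sig[((r - 1) * nspr + 1):(r * nspr)] <- data[from:(from + nspr - 1)]
    }
    gain <- (hdr$phys_max[s] - hdr$phys_min[s]) / (hdr$dig_max[s] - hdr$dig_min[s])
    phys <- hdr$phys_min[s] + (sig - hdr$dig_min[s]) * gain
    out[[k]] <- eeg_record(phys, fs = nspr / hdr$record_dur,
                           source_id = paste0(basename(path), ":", hdr$labels[s]))
  }
  out
}

#' Write EEG records to a minimal EDF file
#'
#' Intended for building small test recordings and round-tripping
#' synthetic data; all records must share a sampling rate and length, and
#' the length must be a whole number of 1-second data records.
#'
#' @param records List of [eeg_record] objects (channel labels from
#'   `source_id`, or `Ch1..ChN` if empty).
#' @param path Output path.
#' @export
write_edf <- function(records, path) {
  stopifnot(length(records) >= 1, all(vapply(records, inherits, TRUE, "eeg_record")))
  fs <- records[[1]]$fs
  n <- length(records[[1]]$samples)
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  for (r in records) {
    if (r$fs != fs || length(r$samples) != n) stop("records must share fs and length")
  }
  if (n %% fs != 0) stop("record length must be a whole number of seconds")
  ns <- length(records)
  n_records <- n / fs
  labels <- vapply(seq_len(ns), function(i) {
    lab <- records[[i]]$source_id
    if (!nzchar(lab)) paste0("Ch", i) else substr(lab, 1, 16)
  }, character(1))
  phys_min <- vapply(records, function(r) floor(min(r$samples, -1)), numeric(1))
  phys_max <- vapply(records, function(r) ceiling(max(r$samples, 1)), numeric(1))
  dig_min <- rep(-32768, ns); dig_max <- rep(32767, ns)

  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(pad("0", 8), pad("synthetic", 80), pad("synthetic", 80),
                   pad("01.01.00", 8), pad("00.00.00", 8),
                   pad(256 + 256 * ns, 8), pad("", 44), pad(n_records, 8),
                   pad("1", 8), pad(ns, 4),
                   paste(pad(labels, 16), collapse = ""),
                   paste(pad(rep("", ns), 80), collapse = ""),
                   paste(pad(rep("uV", ns), 8), collapse = ""),
                   paste(pad(phys_min, 8), collapse = ""),
                   paste(pad(phys_max, 8), collapse = ""),
                   paste(pad(dig_min, 8), collapse = ""),
                   paste(pad(dig_max, 8), collapse = ""),
                   paste(pad(rep("", ns), 80), collapse = ""),
                   paste(pad(rep(fs, ns), 8), collapse = ""),
                   paste(pad(rep("", ns), 32), collapse = "")),
            con, eos = NULL)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      x <- records[[s]]$samples[((r - 1) * fs + 1):(r * fs)]
      dig <- round((x - phys_min[s]) / (phys_max[s] - phys_min[s]) *
                     (dig_max[s] - dig_min[s]) + dig_min[s])
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
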