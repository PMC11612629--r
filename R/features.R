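# The 35-feature multi-domain summary of an EEG segment: five statistics
# over six wavelet sub-band coefficient sets (30 time-frequency features)
# plus Welch log band power in the five clinical bands.

#' Wavelet sub-band statistics
#'
#' The five per-sub-band statistics summarising a set of wavelet
#' coefficients `c_j`, `j = 1..N`:
#' * `stat_lswt`: log-sum, `sum(ln |c_j|)`, with `|c_j|` clamped below at
#'   `1e-12` so zero coefficients stay finite;
#' * `stat_mean_abs`: mean absolute value, `mean(|c_j|)`;
#' * `stat_mean_power`: mean power, `mean(c_j^2)`;
#' * `stat_std`: standard deviation about the mean *absolute* value,
#'   `sqrt(mean((c_j - mean(|c_j|))^2))` — the field-standard variant that
#'   centres on the absolute mean; `center = "conventional"` centres on
#'   the signed mean instead;
#' * `stat_rat`: ratio of absolute sums of two adjacent sub-bands,
#'   `sum(|a_j|) / sum(|b_j|)`, denominator clamped at `1e-12`.
#'
#' @param coeffs,coeffs_a,coeffs_b Numeric coefficient vectors.
#' @param center `"paper"` (absolute-mean centring, default) or
#'   `"conventional"`.
#' @return A single number.
#' @name subband_stats
NULL

#' @rdname subband_stats
#' @export
stat_lswt <- function(coeffs) {
  sum(log(pmax(abs(coeffs), .EPS_CLAMP)))
}

#' @rdname subband_stats
#' @export
stat_mean_abs <- function(coeffs) mean(abs(coeffs))

#' @rdname subband_stats
#' @export
stat_mean_power <- function(coeffs) mean(coeffs^2)

#' @rdname subband_stats
#' @export
stat_std <- function(coeffs, center = c("paper", "conventional")) {
  center <- match.arg(center)
  ctr <- if (center == "paper") mean(abs(coeffs)) else mean(coeffs)
  sqrt(mean((coeffs - ctr)^2))
}

#' @rdname subband_stats
#' @export
stat_rat <- function(coeffs_a, coeffs_b) {
  max(sum(abs(coeffs_a)), .EPS_CLAMP) / max(sum(abs(coeffs_b)), .EPS_CLAMP)
}

#' The five clinical EEG frequency bands
#'
#' Delta 0.1--4, theta 4--8, alpha 8--12, beta 12--30, gamma 30--70 Hz.
#' Bands are treated as half-open `[low, high)` so contiguous bands never
#' double-count a frequency bin.
#'
#' @return Data frame with columns `name`, `low`, `high`.
#' @export
band_scheme <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(0.1, 4, 8, 12, 30),
             high = c(4, 8, 12, 30, 70))
}

#' Welch power spectral density estimate
#'
#' Splits the input into length-`M` windows with the given overlap,
#' applies the taper `w(n)`, computes per-window periodograms normalised
#' by the window power `U = mean(w^2)` (so the estimate is unbiased for
#' the spectral density), and averages them. One-sided density scaling:
#' integrating the returned density over frequency recovers the signal
#' variance for a zero-mean stationary input.
#'
#' @param segment Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param M Window length in samples (default 256).
#' @param overlap Overlap between consecutive windows (default `M/2`).
#' @param window Taper name: `"hamming"` (default), `"hann"`, or
#'   `"rectangular"`.
#' @return Object of class `psd_estimate`: list with `freqs`, `power`,
#'   and `params`.
#' @export
welch_psd <- function(segment, fs, M = 256, overlap = M %/% 2,
                      window = "hamming") {
  segment <- as.numeric(segment)
  N <- length(segment)
  if (M > N) stop("window length M (", M, ") exceeds segment length (", N, ")")
  if (overlap < 0 || overlap >= M) stop("need 0 <= overlap < M")
  w <- switch(window,
    hamming = 0.54 - 0.46 * cos(2 * pi * (0:(M - 1)) / (M - 1)),
    hann = 0.5 - 0.5 * cos(2 * pi * (0:(M - 1)) / (M - 1)),
    rectangular = rep(1, M),
    stop("unknown window: ", window))
  U <- mean(w^2)
  stride <- M - overlap
  starts <- seq(1, N - M + 1, by = stride)
  L <- length(starts)
  n_freq <- M %/% 2 + 1
  acc <- numeric(n_freq)
  for (s in starts) {
    xw <- segment[s:(s + M - 1)] * w
    X <- fft(xw)[seq_len(n_freq)]
    # periodogram as density: |X|^2 / (fs * M * U); U = mean(w^2)
    p <- (Mod(X)^2) / (fs * M * U)
    # one-sided: double all bins except DC and (for even M) Nyquist
    dbl <- rep(2, n_freq)
    dbl[1] <- 1
    if (M %% 2 == 0) dbl[n_freq] <- 1
    acc <- acc + p * dbl
  }
  structure(list(freqs = (seq_len(n_freq) - 1) * fs / M,
                 power = acc / L,
                 params = list(M = M, L = L, overlap = overlap,
                               window = window, U = U, fs = fs)),
            class = "psd_estimate")
}

#' Log band power from a PSD estimate
#'
#' Natural log of the summed spectral power over frequency bins in
#' `[band_low, band_high)`; the sum is clamped below at `1e-12` so silent
#' bands stay finite.
#'
#' @param psd A `psd_estimate` from [welch_psd].
#' @param band_low,band_high Band edges in Hz.
#' @return A single number.
#' @export
band_log_power <- function(psd, band_low, band_high) {
  stopifnot(inherits(psd, "psd_estimate"))
  sel <- psd$freqs >= band_low & psd$freqs < band_high
  if (!any(sel)) stop("no frequency bins in band [", band_low, ", ", band_high, ")")
  log(max(sum(psd$power[sel]), .EPS_CLAMP))
}

#' Feature-extraction configuration
#'
#' @param wavelet Wavelet family for the sub-band decomposition.
#' @param n_levels Decomposition depth (6 coefficient sets at depth 5).
#' @param rat_mode `"cyclic"` (default): six adjacent-band ratios closing
#'   A5 back onto D1, giving the full 35-feature vector; `"adjacent5"`:
#'   only the five strictly adjacent pairs (34 features, the sixth ratio
#'   reported as `NA` and dropped from matrices).
#' @param welch_M,welch_overlap,welch_window Welch parameters (see
#'   [welch_psd]).
#' @param bands Band scheme data frame (see [band_scheme]).
#' @return Object of class `extraction_config`.
#' @export
extraction_config <- function(wavelet = "db4", n_levels = 5,
                              rat_mode = c("cyclic", "adjacent5"),
                              welch_M = 256, welch_overlap = welch_M %/% 2,
                              welch_window = "hamming",
                              bands = band_scheme()) {
  structure(list(wavelet = wavelet, n_levels = n_levels,
                 rat_mode = match.arg(rat_mode), welch_M = welch_M,
                 welch_overlap = welch_overlap, welch_window = welch_window,
                 bands = bands),
            class = "extraction_config")
}

#' Extract the 35-feature vector from one segment
#'
#' Computes, in the canonical order of [feature_names]: the log-sum, mean
#' absolute value, mean power, and standard deviation of each of the six
#' wavelet coefficient sets D1..D5, A5; the six adjacent-band absolute-sum
#' ratios (band i over band i+1, the sixth closing A5 back onto D1); and
#' the Welch log power of the five clinical bands. The gamma band is
#' capped at `0.99 * fs / 2` for sampling rates whose Nyquist frequency
#' falls inside it.
#'
#' @param segment Numeric vector (at least 256 samples with defaults).
#' @param fs Sampling rate in Hz.
#' @param config An [extraction_config].
#' @return Named numeric vector, length 35 (34 for `rat_mode =
#'   "adjacent5"`).
#' @export
extract_feature_vector <- function(segment, fs, config = extraction_config()) {
  stopifnot(inherits(config, "extraction_config"))
  sb <- dwt_subbands(segment, wavelet = config$wavelet, n_levels = config$n_levels)
  cs <- sb$coeffs
  k <- length(cs)
  lswt <- vapply(cs, stat_lswt, numeric(1))
  mn <- vapply(cs, stat_mean_abs, numeric(1))
  abspw <- vapply(cs, stat_mean_power, numeric(1))
  std <- vapply(cs, stat_std, numeric(1))
  rat <- numeric(k)
  for (i in seq_len(k - 1)) rat[i] <- stat_rat(cs[[i]], cs[[i + 1]])
  rat[k] <- if (config$rat_mode == "cyclic") stat_rat(cs[[k]], cs[[1]]) else NA_real_

  psd <- welch_psd(segment, fs, M = config$welch_M,
                   overlap = config$welch_overlap, window = config$welch_window)
  bands <- config$bands
  bp <- vapply(seq_len(nrow(bands)), function(i) {
    band_log_power(psd, bands$low[i], min(bands$high[i], 0.99 * fs / 2))
  }, numeric(1))

  out <- c(lswt, mn, abspw, std, rat, bp)
  names(out) <- feature_names()
  if (config$rat_mode == "adjacent5") out <- out[!is.na(out)]
  out
}

#' Extract the feature matrix of a segment set
#'
#' Row i is [extract_feature_vector] of segment i; labels are carried
#' through unchanged.
#'
#' @param segset A `segment_set`.
#' @param config An [extraction_config].
#' @return Object of class `feature_matrix`: list with `x` (numeric
#'   matrix, canonical column names) and `labels`.
#' @export
extract_feature_matrix <- function(segset, config = extraction_config()) {
  stopifnot(inherits(segset, "segment_set"))
  n <- nrow(segset$segments)
  nms <- if (config$rat_mode == "cyclic") feature_names() else
    setdiff(feature_names(), "RAT_6")
  x <- matrix(NA_real_, nrow = n, ncol = length(nms),
              dimnames = list(NULL, nms))
  for (i in seq_len(n)) {
    x[i, ] <- extract_feature_vector(segset$segments[i, ], segset$fs, config)
  }
  feature_matrix(x, segset$labels)
}

#' Construct a feature matrix container
#'
#' @param x Numeric matrix with named feature columns.
#' @param labels Vector of class labels, one per row.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, labels) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("feature columns must be named")
  if (length(labels) != nrow(x)) stop("labels must align with rows")
  structure(list(x = x, labels = labels), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d segments x %d features; labels: %s\n",
              nrow(x$x), ncol(x$x),
              paste(names(table(x$labels)), table(x$labels),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' Canonical feature names as header plus a final `label` column.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm$x)
  df$label <- fm$labels
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  labels <- df$label
  df$label <- NULL
  feature_matrix(as.matrix(df), as.character(labels))
}
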