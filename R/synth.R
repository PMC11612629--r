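# Surrogate EEG and labelled feature tables with known ground truth.
# The EEG generator emulates the class structure of clinical recordings:
# class identity is carried by band-power composition (alpha-dominant
# healthy background, high-amplitude slow ictal rhythm) and by
# spike-wave transient content, not by any single feature.

#' Specification of a synthetic EEG record
#'
#' A record is the sum of band-limited noise components (white noise
#' filtered into each clinical band, scaled to the requested standard
#' deviation), Poisson-timed biphasic spike-wave transients, and
#' broadband white noise.
#'
#' @param class_label `"healthy"`, `"interictal"`, or `"ictal"`.
#' @param fs Sampling rate in Hz.
#' @param n_samples Record length.
#' @param band_amplitudes Named vector (delta/theta/alpha/beta/gamma) of
#'   per-band standard deviations, in microvolts.
#' @param spike_rate Spike-wave events per second.
#' @param spike_amplitude Peak amplitude of each transient.
#' @param noise_sd Broadband white-noise standard deviation.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return Object of class `synth_eeg_spec`.
#' @export
synth_eeg_spec <- function(class_label = "healthy", fs = 173.61,
                           n_samples = 4097,
                           band_amplitudes = c(delta = 15, theta = 10,
                                               alpha = 40, beta = 10,
                                               gamma = 5),
                           spike_rate = 0, spike_amplitude = 0,
                           noise_sd = 10, seed = 1L) {
  if (any(band_amplitudes < 0)) stop("band amplitudes must be >= 0")
  structure(list(class_label = class_label, fs = fs, n_samples = n_samples,
                 band_amplitudes = band_amplitudes, spike_rate = spike_rate,
                 spike_amplitude = spike_amplitude, noise_sd = noise_sd,
                 seed = seed),
            class = "synth_eeg_spec")
}

#' Default class recipes for the three-class problem
#'
#' Healthy: alpha-dominant background, no transients. Interictal:
#' flatter background with sporadic spike-waves. Ictal: dominant
#' high-amplitude slow (2--4 Hz) rhythm with frequent spike-waves.
#' Amplitudes are chosen so that the full 35-feature profile separates
#' the classes with margin while no single feature does so perfectly.
#'
#' @param fs,n_samples Record geometry (Bonn-like defaults).
#' @return Named list of [synth_eeg_spec] objects.
#' @export
default_class_specs <- function(fs = 173.61, n_samples = 4097) {
  list(
    healthy = synth_eeg_spec("healthy", fs, n_samples,
      band_amplitudes = c(delta = 15, theta = 10, alpha = 40, beta = 10, gamma = 5),
      spike_rate = 0, spike_amplitude = 0, noise_sd = 10),
    interictal = synth_eeg_spec("interictal", fs, n_samples,
      band_amplitudes = c(delta = 20, theta = 15, alpha = 18, beta = 12, gamma = 6),
      spike_rate = 0.5, spike_amplitude = 150, noise_sd = 10),
    ictal = synth_eeg_spec("ictal", fs, n_samples,
      band_amplitudes = c(delta = 120, theta = 25, alpha = 12, beta = 15, gamma = 8),
      spike_rate = 3, spike_amplitude = 250, noise_sd = 10))
}

# White noise filtered into [low, high] Hz and rescaled to unit sd.
band_noise <- function(n, fs, low, high) {
  nyq <- fs / 2
  x <- rnorm(n + 512)  # pad to absorb filter transients
  hi <- min(high, 0.99 * nyq)
  bf <- if (low <= 0.5) {
    signal::butter(4, hi / nyq, type = "low")
  } else {
    signal::butter(4, c(low, hi) / nyq, type = "pass")
  }
  y <- signal::filtfilt(bf, x)[257:(256 + n)]
  s <- sd(y)
  if (s > 0) y / s else y
}

# One period of a 3 Hz biphasic spike-wave transient, unit peak.
spike_waveform <- function(fs, f0 = 3) {
  n <- max(round(fs / f0), 4)
  t <- seq_len(n) / n
  w <- sin(2 * pi * t) * sin(pi * t)  # biphasic, tapered to zero at edges
  w / max(abs(w))
}

#' Generate one synthetic EEG record
#'
#' @param spec A [synth_eeg_spec].
#' @return An [eeg_record] labelled with the spec's class.
#' @export
gen_eeg_record <- function(spec) {
  stopifnot(inherits(spec, "synth_eeg_spec"))
  bands <- band_scheme()
  n <- spec$n_samples
  with_seed(spec$seed, {
    x <- numeric(n)
    for (b in seq_len(nrow(bands))) {
      amp <- spec$band_amplitudes[[bands$name[b]]]
      if (!is.null(amp) && !is.na(amp) && amp > 0) {
        x <- x + amp * band_noise(n, spec$fs, bands$low[b], bands$high[b])
      }
    }
    if (spec$spike_rate > 0 && spec$spike_amplitude > 0) {
      wf <- spike_waveform(spec$fs) * spec$spike_amplitude
      n_events <- rpois(1, spec$spike_rate * n / spec$fs)
      if (n_events > 0) {
        starts <- sort(sample.int(max(n - length(wf), 1), n_events, replace = TRUE))
        for (s in starts) {
          span <- s:min(s + length(wf) - 1, n)
          x[span] <- x[span] + wf[seq_along(span)]
        }
      }
    }
    if (spec$noise_sd > 0) x <- x + rnorm(n, sd = spec$noise_sd)
    eeg_record(x, fs = spec$fs, label = spec$class_label,
               source_id = sprintf("synthetic_%s_seed%d", spec$class_label, spec$seed))
  })
}

#' Generate a class-balanced synthetic EEG dataset
#'
#' `n_per_class` records per class, each with an independent seed derived
#' from `seed` and multiplicative per-record jitter on the band
#' amplitudes (uniform on `1 +/- jitter`).
#'
#' @param n_per_class Records per class.
#' @param base_specs Named list of class recipes
#'   (default [default_class_specs]).
#' @param jitter Relative amplitude jitter (0 disables it).
#' @param seed Master seed.
#' @return List of [eeg_record] objects.
#' @export
gen_eeg_dataset <- function(n_per_class = 100,
                            base_specs = default_class_specs(),
                            jitter = 0.15, seed = 1L) {
  out <- list()
  i <- 0L
  for (cls in names(base_specs)) {
    for (r in seq_len(n_per_class)) {
      i <- i + 1L
      spec <- base_specs[[cls]]
      spec$seed <- derive_seed(seed, i)
      if (jitter > 0) {
        spec$band_amplitudes <- with_seed(derive_seed(seed, 100000L + i),
          spec$band_amplitudes * runif(length(spec$band_amplitudes),
                                       1 - jitter, 1 + jitter))
      }
      out[[i]] <- gen_eeg_record(spec)
    }
  }
  out
}

#' Specification of a labelled synthetic feature table
#'
#' @param n_samples Rows.
#' @param n_features Columns (named `f1..fd`).
#' @param informative_idx Indices of informative columns: Gaussian with
#'   class-dependent means separated by `effect_size` (in units of the
#'   within-class standard deviation, which is 1).
#' @param effect_size Between-adjacent-class mean separation.
#' @param redundant_pairs List of `c(source, copy, rho)` triples: the
#'   copy column is a `rho`-correlated duplicate of the (standardised)
#'   source; `rho = 1` gives an exact duplicate.
#' @param n_classes Number of classes (balanced).
#' @param seed Integer seed.
#' @return Object of class `synth_table_spec`.
#' @export
synth_table_spec <- function(n_samples = 300, n_features = 12,
                             informative_idx = 1:3, effect_size = 2,
                             redundant_pairs = list(), n_classes = 3,
                             seed = 1L) {
  copies <- vapply(redundant_pairs, `[`, numeric(1), 2)
  if (length(intersect(informative_idx, copies)) > 0) {
    stop("redundant copy indices must be disjoint from informative indices")
  }
  for (p in redundant_pairs) {
    if (abs(p[3]) > 1) stop("|rho| must be <= 1")
  }
  structure(list(n_samples = n_samples, n_features = n_features,
                 informative_idx = informative_idx, effect_size = effect_size,
                 redundant_pairs = redundant_pairs, n_classes = n_classes,
                 seed = seed),
            class = "synth_table_spec")
}

#' Generate a labelled feature table with known ground truth
#'
#' Informative columns carry class-dependent means, redundant copies are
#' correlated duplicates of their source, and the rest is pure noise.
#'
#' @param spec A [synth_table_spec].
#' @return List: `features` (a `feature_matrix`), `labels`, and `truth`
#'   (the informative index set and pair map, for assertions).
#' @export
gen_feature_table <- function(spec) {
  stopifnot(inherits(spec, "synth_table_spec"))
  n <- spec$n_samples
  d <- spec$n_features
  K <- spec$n_classes
  with_seed(spec$seed, {
    labels <- sort(rep_len(paste0("c", seq_len(K)), n))
    cls <- as.integer(factor(labels))
    x <- matrix(rnorm(n * d), nrow = n,
                dimnames = list(NULL, paste0("f", seq_len(d))))
    for (j in spec$informative_idx) {
      x[, j] <- x[, j] + (cls - (K + 1) / 2) * spec$effect_size
    }
    for (p in spec$redundant_pairs) {
      src <- as.vector(scale(x[, p[1]]))
      rho <- p[3]
      x[, p[2]] <- rho * src + sqrt(1 - rho^2) * rnorm(n)
    }
    list(features = feature_matrix(x, labels), labels = labels,
         truth = list(informative_idx = spec$informative_idx,
                      redundant_pairs = spec$redundant_pairs))
  })
}
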