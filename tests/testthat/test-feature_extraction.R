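test_that("dyadic decomposition yields six sets, conserves energy, localises tones", {
  set.seed(2)
  x <- rnorm(1024)
  sb <- dwt_subbands(x)
  expect_s3_class(sb, "subband_set")
  expect_length(sb$coeffs, 6)
  # periodized orthonormal transform conserves energy
  expect_equal(sum(unlist(lapply(sb$coeffs, function(c) sum(c^2)))),
               sum(x^2), tolerance = 1e-10)

  z <- dwt_subbands(rep(0, 1024))
  expect_true(all(unlist(z$coeffs) == 0))

  # 4 Hz tone at the Bonn rate: D5 (~2.7-5.4 Hz) dominates the detail sets
  sb4 <- dwt_subbands(tone(4))
  powers <- vapply(sb4$coeffs[1:5], function(c) mean(c^2), numeric(1))
  expect_equal(which.max(powers), 5)

  expect_error(dwt_subbands(rnorm(64), n_levels = 12), "at most")
  expect_error(dwt_subbands(rnorm(256), wavelet = "sym9"), "unknown wavelet")
})

test_that("sub-band statistics match hand arithmetic", {
  expect_equal(stat_lswt(rep(1, 100)), 0)
  expect_equal(stat_lswt(rep(exp(1), 7)), 7)
  expect_equal(stat_lswt(c(2, -2, 4)), 4 * log(2))  # ln2 + ln2 + 2 ln2

  expect_equal(stat_mean_abs(c(-2, 2, -2, 2)), 2)
  expect_equal(stat_mean_abs(rep(0, 5)), 0)
  expect_equal(stat_mean_abs(c(1, -3, 5)), 3)

  expect_equal(stat_mean_power(c(3, 3, 3)), 9)
  expect_equal(stat_mean_power(rep(0, 4)), 0)
  expect_equal(stat_mean_power(c(1, 2, 3)), 14 / 3)

  # absolute-mean centring: sqrt((0+4+0+4)/4) = sqrt(2); conventional is 1
  expect_equal(stat_std(c(1, -1, 1, -1)), sqrt(2))
  expect_equal(stat_std(c(1, -1, 1, -1), center = "conventional"), 1)
  expect_equal(stat_std(c(5, 5, 5)), 0)

  expect_equal(stat_rat(c(1, 2), c(1, 2)), 1)
  expect_equal(stat_rat(c(2, 2), c(1, 1, 1, 1)), 1)  # ratio of sums, not means
  expect_equal(stat_rat(c(1, 1), rep(0, 3)), 2 / 1e-12)
})

test_that("Welch estimate is a calibrated one-sided density", {
  fs <- 100
  expect_equal(sum(welch_psd(rep(0, 1024), fs)$power), 0)

  set.seed(8)
  x <- rnorm(8192)
  p <- welch_psd(x, fs)
  df <- fs / p$params$M
  expect_equal(sum(p$power) * df, var(x), tolerance = 0.1)

  # tone location against a direct DFT oracle
  x10 <- tone(10, fs = BONN_FS)
  p10 <- welch_psd(x10, BONN_FS)
  n <- length(x10)
  dft_freqs <- (0:(n - 1)) * BONN_FS / n
  oracle_peak <- dft_freqs[which.max(Mod(fft(x10))[1:(n %/% 2)])]
  welch_peak <- p10$freqs[which.max(p10$power)]
  expect_lt(abs(welch_peak - oracle_peak), BONN_FS / p10$params$M + 1e-9)
  expect_lt(abs(welch_peak - 10), BONN_FS / p10$params$M + 1e-9)

  expect_error(welch_psd(rnorm(100), fs, M = 256), "exceeds")
})

test_that("averaging more windows reduces the estimator variance", {
  set.seed(3)
  spread <- vapply(c(1, 4, 16), function(L) {
    v <- replicate(30, {
      x <- rnorm(256 * L)
      p <- welch_psd(x, 100, M = 256, overlap = 0)
      mean(p$power[2:128])  # flat-spectrum level estimate
    })
    var(v)
  }, numeric(1))
  expect_true(spread[1] > spread[2])
  expect_true(spread[2] > spread[3])
})

test_that("band log power sums bins in the half-open band and is log-additive", {
  p <- welch_psd(tone(10), BONN_FS)
  b <- band_scheme()
  vals <- vapply(seq_len(5), function(i) {
    band_log_power(p, b$low[i], min(b$high[i], 0.99 * BONN_FS / 2))
  }, numeric(1))
  expect_equal(which.max(vals), 3)  # alpha

  p2 <- welch_psd(tone(10, amplitude = 2), BONN_FS)
  expect_equal(band_log_power(p2, 8, 12) - band_log_power(p, 8, 12),
               log(4), tolerance = 1e-8)

  silent <- welch_psd(rep(0, 1024), BONN_FS)
  expect_equal(band_log_power(silent, 8, 12), log(1e-12))
  expect_error(band_log_power(p, 40.1, 40.6), "no frequency bins")
})

test_that("the extracted vector has 35 named entries and contractual degenerate values", {
  v <- extract_feature_vector(tone(10) + rnorm(1024), BONN_FS)
  expect_length(v, 35)
  expect_identical(names(v), feature_names())
  expect_true(all(is.finite(v)))

  z <- extract_feature_vector(rep(0, 1024), BONN_FS)
  expect_true(all(z[grep("LSWT", names(z))] < 0))        # clamp floor logs
  expect_true(all(z[grep("MEAN|ABS|STD", names(z))] == 0))
  expect_equal(unname(z[grep("RAT", names(z))]), rep(1, 6))  # eps/eps
  expect_true(all(z[grep("power", names(z))] == log(1e-12)))

  seg <- rnorm(1024)
  expect_identical(extract_feature_vector(seg, BONN_FS),
                   extract_feature_vector(seg, BONN_FS))

  v34 <- extract_feature_vector(seg, BONN_FS,
                                extraction_config(rat_mode = "adjacent5"))
  expect_length(v34, 34)
  expect_false("RAT_6" %in% names(v34))
})

test_that("amplitude scaling transforms each feature family as predicted", {
  set.seed(6)
  seg <- rnorm(1024) + tone(10)
  s <- 3
  v1 <- extract_feature_vector(seg, BONN_FS)
  vs <- extract_feature_vector(s * seg, BONN_FS)
  pick <- function(v, fam) v[grep(fam, names(v))]
  expect_equal(pick(vs, "MEAN"), s * pick(v1, "MEAN"), tolerance = 1e-8)
  expect_equal(pick(vs, "^ABS"), s^2 * pick(v1, "^ABS"), tolerance = 1e-8)
  expect_equal(pick(vs, "STD"), s * pick(v1, "STD"), tolerance = 1e-8)
  expect_equal(pick(vs, "RAT"), pick(v1, "RAT"), tolerance = 1e-8)
  n_coeffs <- lengths(dwt_subbands(seg)$coeffs)
  expect_equal(unname(pick(vs, "LSWT") - pick(v1, "LSWT")),
               unname(n_coeffs * log(s)), tolerance = 1e-6)
  expect_equal(unname(pick(vs, "power") - pick(v1, "power")),
               rep(log(s^2), 5), tolerance = 1e-8)
})

test_that("feature matrices are row-wise extractions with labels carried through", {
  rec <- eeg_record(rnorm(4097), fs = BONN_FS, label = "ictal")
  ss <- segment_record(rec)
  fm <- extract_feature_matrix(ss)
  expect_equal(dim(fm$x), c(4, 35))
  expect_identical(colnames(fm$x), feature_names())
  expect_equal(fm$labels, rep("ictal", 4))
  expect_equal(fm$x[2, ], extract_feature_vector(ss$segments[2, ], ss$fs))

  # permuting segments permutes rows identically
  ss2 <- ss
  perm <- c(3, 1, 4, 2)
  ss2$segments <- ss$segments[perm, ]
  ss2$labels <- ss$labels[perm]
  fm2 <- extract_feature_matrix(ss2)
  expect_equal(fm2$x, fm$x[perm, ])

  empty <- ss
  empty$segments <- ss$segments[0, , drop = FALSE]
  empty$labels <- character(0)
  fe <- extract_feature_matrix(empty)
  expect_equal(dim(fe$x), c(0, 35))
  expect_identical(colnames(fe$x), feature_names())

  path <- tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$x, fm$x, tolerance = 1e-12)
  expect_equal(back$labels, fm$labels)
})
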