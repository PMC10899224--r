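test_that("epoch PSDs use the fixed Welch layout and normalize to one", {
  set.seed(1)
  p <- welch_psd(rnorm(1250), 250)
  expect_equal(p$n_segments, 9)                 # (5 - 1) / 0.5 + 1
  expect_equal(p$freqs[2] - p$freqs[1], 250 / 512)

  sp <- epoch_psd(rnorm(250 * 60), 250, 5, "total_0_50")
  expect_equal(rowSums(sp$psd[, sp$freqs <= 50]), rep(1, 12),
               tolerance = 1e-6)
  # white noise: roughly flat in-band
  m <- colMeans(sp$psd)
  inband <- sp$freqs > 5 & sp$freqs < 45
  expect_lt(max(m[inband]) / min(m[inband]), 1.6)

  # a pure tone peaks at the nearest bin
  tone <- sin(2 * pi * 10 * (0:1249) / 250)
  pt <- welch_psd(tone, 250)
  expect_equal(pt$freqs[which.max(pt$psd)], 10, tolerance = 250 / 512)

  # too-short epochs are an error at the welch level
  expect_error(welch_psd(rnorm(100), 250), "shorter than one Welch segment")
})

test_that("Welch band-sum tracks the variance of stationary noise", {
  set.seed(2)
  x <- rnorm(250 * 30, sd = 3)
  p <- welch_psd(x, 250)
  expect_equal(sum(p$psd) * 250 / 512, var(x), tolerance = 0.05 * var(x))
})

test_that("band powers integrate half-open bands and guard empty ones", {
  # uniform psd over 0-50 Hz: delta (1-4) holds 3/50 of the power
  freqs <- seq(0, 50, by = 0.5)
  spec <- list(freqs = freqs, psd = matrix(1 / length(freqs),
                                           nrow = 1, ncol = length(freqs)),
               epochs = data.frame(epoch_index = 0L, t_label_s = 2.5))
  spec$psd <- spec$psd / sum(spec$psd)
  bp <- band_powers(spec, band_scheme("analysis"))
  frac <- sum(freqs >= 1 & freqs < 4) / length(freqs)
  expect_equal(bp$delta, 10 * log10(frac), tolerance = 1e-9)

  # ml scheme: exactly six band values
  bp_ml <- band_powers(spec, "ml")
  expect_equal(setdiff(names(bp_ml),
                       c("epoch_index", "t_label_s")),
               c("delta", "theta", "alpha", "sigma", "high_beta",
                 "low_gamma"))

  # zero in-band power floors at -300 dB
  spec0 <- spec
  spec0$psd[freqs >= 1 & freqs < 4] <- 0
  expect_equal(band_powers(spec0, "analysis")$delta, -300)

  # band outside the frequency range errors
  expect_error(band_powers(list(freqs = seq(0, 10, 0.5),
                                psd = matrix(1, 1, 21),
                                epochs = spec$epochs),
                           list(gamma = c(31, 50))), "outside")
})

test_that("magnitude-squared coherence behaves at its anchors", {
  set.seed(3)
  x <- rnorm(1250)
  m <- welch_msc(x, x, 250)
  expect_equal(m$msc, rep(1, length(m$msc)), tolerance = 1e-6)

  # independent white noise: small mean coherence (segment-count bias only)
  mm <- vapply(1:15, function(i) mean(welch_msc(rnorm(1250), rnorm(1250),
                                                250)$msc), 0)
  expect_lt(mean(mm), 0.35)

  # a shared 6 Hz component peaks within one bin
  sh <- sin(2 * pi * 6 * (0:1249) / 250)
  m6 <- welch_msc(sh + rnorm(1250), sh + rnorm(1250), 250)
  expect_lt(abs(m6$freqs[which.max(m6$msc)] - 6), 250 / 512 + 1e-9)

  # invariance to swap and per-channel scaling
  a <- sh + rnorm(1250); b <- sh + rnorm(1250)
  expect_equal(welch_msc(a, b, 250)$msc, welch_msc(b, a, 250)$msc,
               tolerance = 1e-12)
  expect_equal(welch_msc(a, b, 250)$msc, welch_msc(3 * a, 0.2 * b, 250)$msc,
               tolerance = 1e-9)

  expect_error(welch_msc(rnorm(100), rnorm(99), 250), "equal length")
})

test_that("stage contrasts recover the injected NREM/wake signature", {
  # identical spectra in both stages: difference is identically zero
  vals <- matrix(rep(c(1, 2, 3), each = 6), nrow = 6)
  stg <- rep(c("N2", "W"), 3); nt <- rep("n1", 6)
  d0 <- stage_contrast(vals, stg, nt)
  expect_equal(as.numeric(d0), rep(0, 3))

  # synthetic night: delta difference > 0, beta difference < 0 in cortex
  n <- cached_night(test_cfg(301, dur = 2700))
  bp <- epoch_band_powers(n$clean_recording, n$hypnogram, epoch_len_s = 5,
                          scheme = "analysis")
  cor_rows <- bp$region == "cortex"
  dd <- stage_contrast(bp$delta[cor_rows], bp$stage[cor_rows],
                       bp$night_id[cor_rows], log_transform = FALSE)
  db <- stage_contrast(bp$beta[cor_rows], bp$stage[cor_rows],
                       bp$night_id[cor_rows], log_transform = FALSE)
  expect_gt(dd[[1]], 0)
  expect_lt(db[[1]], 0)

  # a night missing one stage is excluded with a warning
  expect_warning(
    stage_contrast(matrix(1, 2, 2), c("N2", "N2"), c("n1", "n1")),
    "lacks a contrasted stage")
})

test_that("epoch tables carry metadata and drop unscored epochs", {
  n <- cached_night(test_cfg(301, dur = 2700))
  h <- n$hypnogram
  h$stages[3] <- "U"
  h$fine_stages[13:18] <- "U"
  bp <- epoch_band_powers(n$clean_recording, h, epoch_len_s = 30,
                          scheme = "ml")
  expect_false(any(bp$stage == "U"))
  expect_false(2L %in% bp$epoch_index)     # the U epoch is absent
  expect_setequal(unique(bp$hemisphere), c("L", "R"))
  expect_equal(unique(bp$norm_mode), "total_0_50")
})
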