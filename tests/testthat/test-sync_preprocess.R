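test_that("estimate_lag recovers a pure shift exactly and is antisymmetric", {
  p <- make_accel_pair(1, dur_s = 150, lag_s = 2.0)
  r <- estimate_lag(p$a, p$b, common_fs = 50, max_lag_s = 10)
  expect_equal(r$lag_s, 2.0, tolerance = 1 / 50 + 1e-9)
  expect_gt(r$peak_ncc, 0.9)
  expect_true(r$confident)

  # identical traces: zero lag
  r0 <- estimate_lag(p$a, p$a, common_fs = 50, max_lag_s = 10)
  expect_equal(r0$lag_s, 0)
  expect_equal(r0$peak_ncc, 1, tolerance = 1e-9)

  # antisymmetry within one sample
  rab <- estimate_lag(p$a, p$b, common_fs = 50, max_lag_s = 10)
  rba <- estimate_lag(p$b, p$a, common_fs = 50, max_lag_s = 10)
  expect_lte(abs(rab$lag_s + rba$lag_s), 1 / 50 + 1e-9)

  expect_error(estimate_lag(p$a, p$b, common_fs = 50, max_lag_s = 100),
               "insufficient overlap")
})

test_that("independent traces are flagged low-confidence", {
  flags <- vapply(1:20, function(s) {
    p <- make_accel_pair(100 + s, dur_s = 120, shared = FALSE)
    estimate_lag(p$a, p$b, common_fs = 50, max_lag_s = 10)$confident
  }, TRUE)
  expect_gte(mean(!flags), 0.95)
})

test_that("conditioning passes the band and rejects drift", {
  fs <- 250
  t <- 0:(fs * 30 - 1) / fs
  mk <- function(x) new_recording(matrix(x, nrow = 1), fs,
                                  data.frame(label = "c", region = "cortex",
                                             hemisphere = "L"))
  # 10 Hz unit tone: amplitude within the cascaded design ripple
  out <- condition_signal(mk(sin(2 * pi * 10 * t)), 250)
  amp <- max(abs(out$samples[1, 2000:5000]))
  expect_gt(amp, 10^(-4 / 20))      # <= 1 dB per pass, 4 zero-phase passes
  expect_lt(amp, 1.01)
  # 0.1 Hz drift attenuated by >= 60 dB
  out <- condition_signal(mk(sin(2 * pi * 0.1 * t)), 250)
  expect_lt(20 * log10(max(abs(out$samples[1, 2000:5000]))), -60)
  # z-score flag
  set.seed(4)
  out <- condition_signal(mk(rnorm(fs * 30, sd = 7, mean = 3)), 250,
                          zscore = TRUE)
  expect_equal(mean(out$samples[1, ]), 0, tolerance = 1e-9)
  expect_equal(sd(out$samples[1, ]), 1, tolerance = 1e-9)
  # design error when the target rate cannot carry the passband
  expect_error(condition_signal(mk(rnorm(fs * 30)), target_fs = 150),
               "design error")
  # non-standard input rates warn but resample
  rec500 <- new_recording(matrix(rnorm(300 * 2), nrow = 1), 300,
                          data.frame(label = "c", region = "cortex",
                                     hemisphere = "L"))
  expect_warning(condition_signal(rec500, 250), "unexpected sampling rate")
})

test_that("spike excision applies the 5x-median rule with guard padding", {
  fs <- 250
  # constant signal: median 0 handled, empty mask
  r <- detect_and_excise_spikes(rep(0, fs * 60), rep(0, fs * 60), fs)
  expect_equal(nrow(r$mask$intervals), 0)

  # engineered exceedance on [10, 12] s flagged
  set.seed(5)
  x <- rnorm(fs * 60)
  x[(10 * fs):(12 * fs)] <- x[(10 * fs):(12 * fs)] * sqrt(8)
  r <- detect_and_excise_spikes(x, rnorm(fs * 60), fs)
  expect_gt(nrow(r$mask$intervals), 0)
  expect_true(any(r$mask$intervals$start_s <= 10.1 &
                    r$mask$intervals$stop_s >= 11.9))

  # large transient at t = 100 s masked in BOTH channels; outside untouched
  set.seed(6)
  x <- rnorm(fs * 200)
  y <- rnorm(fs * 200)
  x[(100 * fs):(100 * fs + 50)] <- 20 * max(abs(x))
  r <- detect_and_excise_spikes(x, y, fs)
  m <- mask_logical(r$mask, length(x), fs)
  expect_true(all(m[(100 * fs):(100 * fs + 50)]))
  expect_identical(r$subcort[!m], x[!m])
  expect_identical(r$cort[!m], y[!m])
  expect_true(all(r$subcort[m] == 0) && all(r$cort[m] == 0))
  # intervals sorted, non-overlapping
  iv <- r$mask$intervals
  if (nrow(iv) > 1) expect_true(all(iv$start_s[-1] > iv$stop_s[-nrow(iv)]))
})

test_that("seed templates are recovered from QRS-contaminated signal only", {
  fs <- 250
  qrs_true <- sleepdbs:::.qrs_shape(fs, 0.08)
  contaminated <- function(seed, dur) {
    rec <- new_recording(
      matrix(sleepdbs:::with_seed(seed, sleepdbs:::.pink_noise(dur * fs, 5)),
             nrow = 1),
      fs, data.frame(label = "s", region = "subcortex", hemisphere = "L"))
    cfg <- synth_config(seed = seed, night_dur_s = max(600, dur),
                        ecg = list(rate_bpm = 70, amp_uv = 60,
                                   qrs_width_s = 0.08),
                        spikes = list(rate_per_hr = 0, amp_uv = 0))
    inject_artifacts(rec, cfg, seed = seed)$recording$samples[1, ]
  }
  st <- build_seed_template(contaminated(21, 600), fs)
  expect_false(is.null(st))
  expect_gte(template_max_ncc(st$seed$waveform, qrs_true), 0.8)

  # clean pink noise yields no template (checked over several nights)
  nulls <- vapply(1:6, function(s) {
    x <- sleepdbs:::with_seed(s, sleepdbs:::.pink_noise(600 * fs, 5))
    is.null(build_seed_template(x, fs))
  }, TRUE)
  expect_gte(mean(nulls), 0.9)

  # 25 min: trailing 5 min appended to the second window
  st25 <- build_seed_template(contaminated(22, 1500), fs)
  expect_false(is.null(st25))
  expect_lte(length(st25$window_templates), 2)
})

test_that("the acceptance gate thresholds the max NCC against the seed", {
  # brute-force oracle for the max normalized cross-correlation over shifts
  brute_max_ncc <- function(a, b) {
    a <- a - mean(a); b <- b - mean(b)
    n <- length(a) + length(b)
    ap <- c(a, rep(0, n - length(a))); bp <- c(b, rep(0, n - length(b)))
    best <- -1
    for (l in -(n - 1):(n - 1)) {
      bs <- if (l >= 0) c(rep(0, l), bp[1:(n - l)])
        else c(bp[(1 - l):n], rep(0, -l))
      best <- max(best, sum(ap * bs) / sqrt(sum(ap^2) * sum(bp^2)))
    }
    best
  }
  set.seed(31)
  s <- sleepdbs:::.qrs_shape(250, 0.08)
  u <- rnorm(length(s))
  # calibrate mixtures to oracle max-NCC 0.85 and 0.95 by bisection
  mix_at <- function(target) {
    lo <- 0; hi <- 1
    for (i in 1:40) {
      al <- (lo + hi) / 2
      m <- brute_max_ncc(al * s / sd(s) + (1 - al) * u / sd(u), s)
      if (m < target) lo <- al else hi <- al
    }
    (lo + hi) / 2
  }
  for (target in c(0.85, 0.95)) {
    al <- mix_at(target)
    cand <- al * s / sd(s) + (1 - al) * u / sd(u)
    expect_equal(brute_max_ncc(cand, s), target, tolerance = 5e-3)
    g <- accept_template(cand, s, threshold = 0.9)
    expect_equal(g$max_ncc, brute_max_ncc(cand, s), tolerance = 1e-6)
    expect_identical(g$accepted, target >= 0.9)
  }
})

test_that("a refined template unlike the seed is rejected in favour of it", {
  fs <- 250
  set.seed(33)
  # events whose true shape is a slow half-sine, very unlike the QRS seed:
  # the adaptive loop converges onto them and must be gated out
  n <- 600 * fs
  x <- rnorm(n, sd = 1)
  shape <- sin(pi * seq(0, 1, length.out = 20)) * 12
  ev_true <- seq(2 * fs, n - 2 * fs, by = round(0.85 * fs))
  for (p in ev_true) x[p:(p + 19)] <- x[p:(p + 19)] + shape
  seed <- sleepdbs:::new_ecg_template(sleepdbs:::.qrs_shape(fs, 0.08), "seed")
  r <- remove_ecg(x, fs, seed)
  expect_identical(r$template$origin, "seed")
  expect_false(r$template$accepted)
  expect_lt(r$template$max_ncc_vs_seed, 0.9)
})

test_that("ECG removal leaves clean signals untouched", {
  fs <- 250
  seed <- sleepdbs:::new_ecg_template(sleepdbs:::.qrs_shape(fs, 0.08), "seed")
  x <- sleepdbs:::with_seed(8, sleepdbs:::.pink_noise(600 * fs, 5))
  r <- remove_ecg(x, fs, seed)
  expect_identical(r$cleaned, x)
  expect_length(r$event_times, 0)
  # degenerate template is an input error
  expect_error(sleepdbs:::new_ecg_template(rep(0, 20), "seed"), "degenerate")
})

test_that("ECG removal strips the artifact while sparing neural beta", {
  n <- cached_night(test_cfg(301, dur = 2700))
  fs <- n$recording$fs
  si <- which(n$recording$channels$region == "subcortex")[1]
  x <- n$recording$samples[si, ]
  st <- build_seed_template(x, fs)
  expect_false(is.null(st))
  r <- remove_ecg(x, fs, st$seed)
  # events found near the injected beat count
  expect_gt(length(r$event_times),
            0.8 * length(n$truth$ecg_event_times))
  clean <- n$clean_recording$samples[si, ]
  pw <- function(v) welch_psd(v, fs, seg_len_s = 4, nfft = 2048)
  pc <- pw(clean); pd <- pw(x); pr <- pw(r$cleaned)
  hr <- 70 / 60
  harm <- unlist(lapply(1:40, function(k)
    which(abs(pc$freqs - k * hr) < 0.15)))
  red <- 1 - (sum(pr$psd[harm]) - sum(pc$psd[harm])) /
    (sum(pd$psd[harm]) - sum(pc$psd[harm]))
  expect_gte(red, 0.7)
  bsel <- pc$freqs >= 13 & pc$freqs < 31
  expect_lte(abs(sum(pr$psd[bsel]) - sum(pc$psd[bsel])) / sum(pc$psd[bsel]),
             0.1)
  # subtraction only touches samples at detected events
  touched <- logical(length(x))
  L <- length(r$template$waveform)
  for (tt in r$event_times) {
    i0 <- round(tt * fs) + 1
    touched[i0:min(i0 + L - 1, length(x))] <- TRUE
  }
  expect_identical(r$cleaned[!touched], x[!touched])
})
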