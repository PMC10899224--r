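test_that("the same seed reproduces a night bit for bit", {
  cfg <- test_cfg(42, dur = 600)
  n1 <- generate_night(cfg)
  n2 <- generate_night(cfg)
  expect_identical(n1, n2)
  expect_identical(generate_hypnogram(cfg), generate_hypnogram(cfg))
  # truth plumbing
  expect_equal(n1$truth$coupling_lag_s, cfg$coupling_lag_s)
  expect_equal(n1$truth$coupling_gain, cfg$coupling_gain)
  expect_equal(n1$truth$accel_lag_s, cfg$accel_lag_s)
})

test_that("default configuration yields a full night with matched parts", {
  cfg <- synth_config(seed = 5, night_dur_s = 1200)
  n <- generate_night(cfg)
  expect_equal(nrow(n$recording$samples), 4)
  expect_equal(ncol(n$recording$samples), 1200 * cfg$fs)
  expect_length(n$hypnogram$stages, 1200 / 30)
  expect_length(n$hypnogram$fine_stages, 1200 / 5)
  expect_setequal(n$recording$channels$region, c("cortex", "subcortex"))
})

test_that("no N1 run is shorter than the scoring minimum", {
  lens <- unlist(lapply(1:120, function(s) {
    h <- generate_hypnogram(test_cfg(s, dur = 3600))
    r <- rle(h$stages)
    r$lengths[r$values == "N1"]
  }))
  expect_gt(length(lens), 50)
  expect_true(all(lens >= 3))
})

test_that("wake-bout dwell means are recovered from the fine track", {
  bouts <- unlist(lapply(1:150, function(s) {
    h <- generate_hypnogram(test_cfg(s, dur = 7200))
    fine <- expand_stages(h)
    sleep_started <- cumsum(fine != "W") > 0
    r <- rle(fine[sleep_started])
    # interior wake bouts only (a trailing bout is truncated by night end)
    keep <- r$values == "W" & seq_along(r$values) < length(r$values)
    r$lengths[keep] * 5
  }))
  expect_gt(length(bouts), 200)
  expect_lt(abs(mean(bouts) - 120) / 120, 0.15)
})

test_that("artifact injection keeps exact ground-truth bookkeeping", {
  set.seed(9)
  rec <- new_recording(matrix(rnorm(2 * 60 * 250, sd = 5), nrow = 2), 250,
                       data.frame(label = c("c", "s"),
                                  region = c("cortex", "subcortex"),
                                  hemisphere = c("L", "L")))
  cfg <- synth_config(seed = 1, night_dur_s = 600,
                      ecg = list(rate_bpm = 60, amp_uv = 30,
                                 qrs_width_s = 0.08),
                      spikes = list(rate_per_hr = 60, amp_uv = 150))
  out <- inject_artifacts(rec, cfg, seed = 11)
  # 60 bpm over 60 s with 10% jitter: 60 +/- 2 beats
  expect_gte(length(out$truth$ecg_event_times), 58)
  expect_lte(length(out$truth$ecg_event_times), 62)
  # artifacts only touch the subcortical channel
  expect_identical(out$recording$samples[1, ], rec$samples[1, ])
  expect_false(identical(out$recording$samples[2, ], rec$samples[2, ]))
  # samples outside every injected event/interval are untouched
  touched <- logical(ncol(rec$samples))
  for (tt in out$truth$ecg_event_times) {
    i0 <- round(tt * 250) + 1
    touched[i0:min(i0 + 25, length(touched))] <- TRUE
  }
  iv <- out$truth$spike_intervals
  for (k in seq_len(nrow(iv)))
    touched[(round(iv$start_s[k] * 250) + 1):
              min(round(iv$stop_s[k] * 250) + 1, length(touched))] <- TRUE
  expect_identical(out$recording$samples[2, !touched],
                   rec$samples[2, !touched])

  # zero amplitudes: identity
  cfg0 <- synth_config(seed = 1, night_dur_s = 600,
                       ecg = list(rate_bpm = 60, amp_uv = 0,
                                  qrs_width_s = 0.08),
                       spikes = list(rate_per_hr = 60, amp_uv = 0))
  out0 <- inject_artifacts(rec, cfg0, seed = 11)
  expect_identical(out0$recording$samples, rec$samples)
  expect_length(out0$truth$ecg_event_times, 0)
  expect_equal(nrow(out0$truth$spike_intervals), 0)
})

test_that("stage-gated spectra follow the canonical sleep ordering", {
  # seed chosen so the short night visits every stage including N3
  n <- cached_night(test_cfg(303, dur = 2700))
  bp <- epoch_band_powers(n$clean_recording, n$hypnogram, epoch_len_s = 5,
                          scheme = "analysis")
  avg <- function(region, stage, band) {
    rows <- bp$region == region & bp$stage %in% stage
    mean(bp[[band]][rows])
  }
  for (reg in c("cortex", "subcortex")) {
    expect_gt(avg(reg, "N3", "delta"), avg(reg, "W", "delta"))
    expect_gt(avg(reg, "W", "beta"), avg(reg, c("N2", "N3"), "beta"))
  }
  # within an N3 segment, delta dominates beta by construction (cortex)
  fine <- expand_stages(n$hypnogram)
  i3 <- which(fine == "N3")[5]
  seg <- n$clean_recording$samples[1, ((i3 - 1) * 5 * 250 + 1):(i3 * 5 * 250)]
  p <- welch_psd(seg, 250)
  expect_gt(sum(p$psd[p$freqs >= 1 & p$freqs < 4]),
            sum(p$psd[p$freqs >= 13 & p$freqs < 31]))
})

test_that("written night fixtures are readable and consistent", {
  n <- cached_night(test_cfg(301, dur = 2700))
  dir <- withr::local_tempdir()
  write_night(n, dir)
  rec <- read_recording(file.path(dir, "fp.edf"))
  h <- read_hypnogram(file.path(dir, "hypnogram.csv"),
                      file.path(dir, "hypnogram_fine.csv"))
  expect_equal(dim(rec$samples), dim(n$recording$samples))
  expect_identical(h$stages, n$hypnogram$stages)
  expect_identical(h$fine_stages, n$hypnogram$fine_stages)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tr$coupling_lag_s, n$truth$coupling_lag_s)
})
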