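## Synthetic-night generator: semi-Markov hypnogram, stage-gated narrowband
## field potentials with a controllable subcortical-beta/cortical-delta
## coupling and pre-awakening beta ramp, injected ECG/spike artifacts, and a
## lagged accelerometer pair. All injected structure is returned as queryable
## ground truth so every pipeline stage is testable by parameter recovery.

#' Configuration for a synthetic night
#'
#' Defaults emulate the study conditions of a multi-night at-home recording:
#' 250 Hz field potentials, ~8 h nights, ~2 min spontaneous awakenings, a
#' negative subcortical-beta to cortical-delta coupling acting with a
#' positive lag (subcortical beta leads), a 10 s pre-awakening beta ramp,
#' QRS-shaped cardiac artifacts on subcortical channels, sparse large spikes,
#' and a known inter-device clock lag between the implant and headband
#' accelerometers.
#'
#' @param seed integer RNG seed; the whole night is reproducible given it.
#' @param fs field-potential sampling rate, Hz.
#' @param night_dur_s night duration, seconds (multiple of 30).
#' @param stage_dwell_means_s named list of mean continuous stage-bout
#'   durations in seconds; `W_start` is pre-sleep wake, `W` a spontaneous
#'   awakening.
#' @param min_n1_run_epochs minimum N1 run length in 30 s epochs (the scoring
#'   convention requires 3 consecutive epochs to classify N1).
#' @param band_amp data.frame (`region`, `stage`, `band`, `amp_uv`) of
#'   oscillation amplitudes (standard deviations, microvolts); defaults via
#'   [default_band_amp()].
#' @param coupling_gain dimensionless gain of the subcortical-beta envelope
#'   onto the cortical-delta envelope (negative = inverse coupling).
#' @param coupling_lag_s coupling delay in seconds; positive means
#'   subcortical beta leads cortical delta.
#' @param prewake_ramp list(`lead_s`, `gain`): subcortical beta amplitude
#'   ramps from baseline to `(1 + gain)` x baseline over the `lead_s` seconds
#'   preceding each fine-label awakening.
#' @param ecg list(`rate_bpm`, `amp_uv`, `qrs_width_s`) for the injected
#'   cardiac artifact on subcortical channels.
#' @param spikes list(`rate_per_hr`, `amp_uv`) for sparse large transients on
#'   subcortical channels.
#' @param accel_lag_s headband clock lag relative to the implant, seconds.
#' @param pink_noise_amp 1/f background standard deviation, microvolts.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         fs = 250,
                         night_dur_s = 8 * 3600,
                         stage_dwell_means_s = list(
                           W_start = 420, N1 = 90, N2 = 210, N3 = 270,
                           R = 540, W = 120),
                         min_n1_run_epochs = 3L,
                         band_amp = default_band_amp(),
                         coupling_gain = -0.5,
                         coupling_lag_s = 5,
                         prewake_ramp = list(lead_s = 10, gain = 1),
                         ecg = list(rate_bpm = 70, amp_uv = 60,
                                    qrs_width_s = 0.08),
                         spikes = list(rate_per_hr = 20, amp_uv = 200),
                         accel_lag_s = 1.5,
                         pink_noise_amp = 5) {
  stopifnot(fs > 0, night_dur_s >= 60, night_dur_s %% 30 == 0,
            all(unlist(stage_dwell_means_s) > 0))
  structure(as.list(environment()), class = "synth_config")
}

#' Default stage-gated oscillation amplitudes
#'
#' Amplitudes (microvolt standard deviations of the band-limited carriers)
#' chosen so that delta dominates deep NREM and beta dominates wakefulness in
#' both regions, with the cortical delta and subcortical beta contrasts the
#' strongest -- the qualitative spectral ordering of cortico-basal sleep.
#'
#' @return data.frame with columns `region`, `stage`, `band`, `amp_uv`.
#' @export
default_band_amp <- function() {
  g <- expand.grid(region = c("cortex", "subcortex"),
                   stage = c("W", "N1", "N2", "N3", "R"),
                   band = c("delta", "theta", "alpha", "beta"),
                   stringsAsFactors = FALSE)
  # Subcortical amplitudes are stage-flat across N2 vs N3 (all bands): the
  # subcortical spectrum is normalized by its 0-50 Hz total downstream, so
  # any N2/N3 stage asymmetry there would leak into the normalized beta
  # series and fake a beta-delta correlation even at zero coupling gain.
  # Within NREM the subcortical beta envelope is driven by the coupling
  # process (and pre-wake ramp) alone.
  # cortical delta is kept moderate relative to the other cortical bands so
  # that the exclude-beta normalizer is not dominated by delta itself, which
  # would compress the observable delta dynamics
  amp <- c(
    cortex = c(W = 3,  N1 = 4,   N2 = 6,  N3 = 9,  R = 3.5),  # delta
    subcortex = c(W = 2.5, N1 = 4, N2 = 6.5, N3 = 6.5, R = 3),
    cortex = c(W = 3,  N1 = 5,   N2 = 4,  N3 = 3,  R = 4),    # theta
    subcortex = c(W = 2, N1 = 3, N2 = 2.25, N3 = 2.25, R = 2.5),
    cortex = c(W = 6,  N1 = 3,   N2 = 2,  N3 = 1.5, R = 4),   # alpha
    subcortex = c(W = 3, N1 = 2, N2 = 1.35, N3 = 1.35, R = 2),
    cortex = c(W = 7,  N1 = 4,   N2 = 3,  N3 = 2,  R = 4),    # beta
    subcortex = c(W = 8, N1 = 5, N2 = 3.5, N3 = 3.5, R = 4))
  key <- interaction(g$band, g$region, g$stage)
  ord <- order(match(g$band, c("delta", "theta", "alpha", "beta")),
               match(g$region, c("cortex", "subcortex")),
               match(g$stage, c("W", "N1", "N2", "N3", "R")))
  g <- g[ord, ]
  g$amp_uv <- as.numeric(amp)
  rownames(g) <- NULL
  g
}

SYNTH_BANDS <- list(delta = c(1, 4), theta = c(4, 8),
                    alpha = c(8, 13), beta = c(13, 31))

## Run code under a scoped seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max, kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  force(code)
}

## Continuous semi-Markov stage trajectory for one night.
.sample_trajectory <- function(cfg) {
  dw <- cfg$stage_dwell_means_s
  n1_min_s <- cfg$min_n1_run_epochs * 30
  draw_dwell <- function(stage) {
    m <- if (stage == "W_start") dw$W_start else dw[[stage]]
    d <- stats::rexp(1, 1 / m)
    if (stage == "N1") d <- max(d, n1_min_s)
    max(d, 5)
  }
  # transition kernel (rows sum to 1) chosen to yield on the order of ten
  # valid N2/N3 -> wake transitions per 8 h night
  nxt <- function(stage) {
    switch(stage,
      W_start = "N1",
      W = sample(c("N1", "N2"), 1, prob = c(0.4, 0.6)),
      N1 = "N2",
      N2 = sample(c("N3", "R", "W"), 1, prob = c(0.5, 0.3, 0.2)),
      N3 = sample(c("N2", "W"), 1, prob = c(0.65, 0.35)),
      R = sample(c("N2", "W"), 1, prob = c(0.65, 0.35)))
  }
  t <- 0; stage <- "W_start"
  starts <- numeric(0); stops <- numeric(0); stages <- character(0)
  while (t < cfg$night_dur_s) {
    d <- draw_dwell(stage)
    starts <- c(starts, t); stops <- c(stops, t + d)
    stages <- c(stages, if (stage == "W_start") "W" else stage)
    t <- t + d
    stage <- nxt(stage)
  }
  stops[length(stops)] <- cfg$night_dur_s
  data.frame(stage = stages, start_s = starts, stop_s = stops)
}

.label_grid <- function(traj, epoch_len_s, total_dur_s) {
  mids <- epoch_grid(total_dur_s, epoch_len_s)$t_label_s
  idx <- findInterval(mids, traj$start_s)
  traj$stage[idx]
}

#' Generate a synthetic hypnogram
#'
#' Samples a continuous semi-Markov stage trajectory (pre-sleep wake, NREM
#' cycling through N1/N2/N3 and REM, spontaneous awakenings; exponential
#' dwells truncated so every N1 bout spans at least `min_n1_run_epochs`
#' epochs) and scores it twice: 30 s epochs labelled by the stage at the
#' epoch midpoint (the automated-scorer view) and a 5 s fine track (the
#' re-scored awakening ground truth).
#'
#' @param cfg a [synth_config()].
#' @return a [new_hypnogram()] with `fine_stages`.
#' @export
generate_hypnogram <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    traj <- .sample_trajectory(cfg)
    coarse <- .label_grid(traj, 30, cfg$night_dur_s)
    fine <- .label_grid(traj, 5, cfg$night_dur_s)
    # a night-end truncation can leave a too-short visible N1 run: absorb it
    r <- rle(coarse)
    if (length(r$lengths) > 1) {
      k <- length(r$lengths)
      if (r$values[k] == "N1" && r$lengths[k] < cfg$min_n1_run_epochs) {
        tail_idx <- (length(coarse) - r$lengths[k] + 1):length(coarse)
        coarse[tail_idx] <- r$values[k - 1]
        fine_idx <- ((min(tail_idx) - 1) * 6 + 1):length(fine)
        fine[fine_idx] <- r$values[k - 1]
      }
    }
    new_hypnogram(coarse, fine_stages = fine)
  })
}

.movavg <- function(x, k) {
  # centered moving average via cumulative sums, edge-renormalized
  k <- max(1L, as.integer(k))
  half <- k %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

.pink_noise <- function(n, amp) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # symmetric frequency index
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  amp * x / stats::sd(x)
}

## Narrowband Gaussian-noise carrier synthesized in the frequency domain:
## white-noise spectrum shaped by a band mask with raised-cosine edges
## (transition width 15% of each corner), unit variance.
.band_carrier <- function(n, fs, band) {
  X <- stats::fft(stats::rnorm(n))
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)                     # fold to [0, fs/2]
  w <- c(0.15 * band[1], 0.15 * band[2])
  mask <- rep(0, n)
  rise <- f >= band[1] - w[1] & f < band[1]
  mask[rise] <- 0.5 - 0.5 * cos(pi * (f[rise] - band[1] + w[1]) / w[1])
  mask[f >= band[1] & f <= band[2]] <- 1
  fall <- f > band[2] & f <= band[2] + w[2]
  mask[fall] <- 0.5 + 0.5 * cos(pi * (f[fall] - band[2]) / w[2])
  x <- Re(stats::fft(X * mask, inverse = TRUE) / n)
  x / stats::sd(x)
}

## Linear interpolation of per-epoch (5 s) values onto the sample grid,
## anchored at epoch midpoints: a continuous envelope with no steps.
.upsample_epochs <- function(vals, fs, n) {
  mids <- (seq_along(vals) - 0.5) * 5 * fs
  stats::approx(mids, vals, xout = seq_len(n), rule = 2)$y
}

## Per-sample amplitude envelope from 5 s stage labels.
.stage_envelope <- function(fine, amps_by_stage, fs) {
  a <- amps_by_stage[fine]
  a[is.na(a)] <- 0
  .upsample_epochs(a, fs, length(fine) * 5 * fs)
}

## Fine-track awakening onset times (s): W segments preceded by N2/N3.
.awakening_times <- function(fine) {
  r <- rle(fine)
  stops <- cumsum(r$lengths)
  starts <- c(0, stops[-length(stops)])
  w <- which(r$values == "W")
  w <- w[w > 1 & r$values[pmax(w - 1, 1)] %in% c("N2", "N3")]
  starts[w] * 5
}

#' Synthesize artifact-free field potentials for a night
#'
#' Four channels (cortex/subcortex x L/R): 1/f background plus stage-gated
#' band-limited Gaussian oscillations. Within the whole night the cortical
#' delta envelope is modulated as
#' `1 + coupling_gain * z(t - coupling_lag_s)` where `z` is the (zero-mean)
#' slow fluctuation driving the subcortical beta envelope `1 + z(t)`, so the
#' injected coupling and its lead-lag are recoverable from N2/N3 epochs. The
#' subcortical beta amplitude additionally ramps up over
#' `prewake_ramp$lead_s` seconds before each fine-label awakening.
#'
#' @param h hypnogram with fine stages (see [generate_hypnogram()]).
#' @param cfg a [synth_config()].
#' @return an [new_recording()] object.
#' @export
synthesize_clean_fp <- function(h, cfg) {
  stopifnot(inherits(h, "hypnogram"), inherits(cfg, "synth_config"))
  fine <- expand_stages(h)
  fs <- cfg$fs
  n <- length(fine) * 5 * fs
  with_seed(cfg$seed + 1L, {
    # slow coupling driver z at 5 s resolution -> per-sample; modulation
    # depth 0.5 makes the injected coupling the dominant within-NREM delta
    # modulator, as for the observed overnight rank correlations
    z_epoch <- gaussian_smooth(stats::rnorm(length(fine)), 12)
    z_epoch <- z_epoch / stats::sd(z_epoch) * 0.5
    z_epoch <- pmin(pmax(z_epoch, -0.9), 0.9)
    z <- .upsample_epochs(z_epoch, fs, n)
    lag_n <- round(cfg$coupling_lag_s * fs)
    z_lagged <- if (lag_n == 0) z
      else if (lag_n > 0) c(rep(z[1], lag_n), z[seq_len(n - lag_n)])
      else c(z[(1 - lag_n):n], rep(z[n], -lag_n))

    # pre-awakening ramp multiplier on subcortical beta amplitude
    ramp <- rep(1, n)
    lead <- cfg$prewake_ramp$lead_s
    if (cfg$prewake_ramp$gain != 0 && lead > 0) {
      for (tw in .awakening_times(fine)) {
        i0 <- max(1L, round((tw - lead) * fs) + 1L)
        i1 <- min(n, round(tw * fs))
        if (i1 > i0)
          ramp[i0:i1] <- 1 + cfg$prewake_ramp$gain *
            seq(0, 1, length.out = i1 - i0 + 1L)
      }
    }

    # slow log-normal per-band amplitude fluctuation (sd ~3 dB, ~1 min
    # timescale), the within-stage variability real band powers show; the
    # two coupling-carrying envelopes (subcortical beta, cortical delta)
    # are excluded so the injected coupling stays the only driver there
    slow_mod <- function(sd_log = 0.35) {
      m <- gaussian_smooth(stats::rnorm(length(fine)), 12)
      .upsample_epochs(exp(sd_log * m / stats::sd(m)), fs, n)
    }
    chans <- expand.grid(hemisphere = c("L", "R"),
                         region = c("cortex", "subcortex"),
                         stringsAsFactors = FALSE)[, 2:1]
    samples <- matrix(0, nrow = 4, ncol = n)
    for (ci in seq_len(4)) {
      reg <- chans$region[ci]
      x <- .pink_noise(n, cfg$pink_noise_amp)
      for (bd in names(SYNTH_BANDS)) {
        ba <- cfg$band_amp[cfg$band_amp$region == reg &
                             cfg$band_amp$band == bd, ]
        amps <- stats::setNames(ba$amp_uv, ba$stage)
        env <- .stage_envelope(fine, amps, fs)
        if (reg == "cortex" && bd == "delta")
          env <- env * pmax(1 + cfg$coupling_gain * z_lagged, 0.05)
        else if (reg == "subcortex" && bd == "beta")
          env <- env * (1 + z) * ramp
        else if (reg == "subcortex" && bd == "delta")
          # gentle: subcortical delta dominates the 0-50 Hz normalizer of
          # the beta predictor, so deep modulation here would masquerade as
          # beta dynamics
          env <- env * slow_mod(0.15)
        else env <- env * slow_mod()
        x <- x + env * .band_carrier(n, fs, SYNTH_BANDS[[bd]])
      }
      samples[ci, ] <- x
    }
    new_recording(samples, fs,
                  data.frame(label = paste(chans$region, chans$hemisphere,
                                           sep = "_"),
                             region = chans$region,
                             hemisphere = chans$hemisphere),
                  night_id = paste0("synth", cfg$seed))
  })
}

.qrs_shape <- function(fs, width_s) {
  # three triangular lobes: small Q, dominant R, small S
  n <- max(6L, round(width_s * fs))
  nq <- max(1L, round(n / 4)); ns_ <- max(1L, round(n / 4))
  nr <- n - nq - ns_
  tri <- function(m) {
    if (m == 1) return(1)
    peak <- (m + 1) / 2
    1 - abs(seq_len(m) - peak) / peak
  }
  c(-0.25 * tri(nq), tri(nr), -0.3 * tri(ns_))
}

#' Inject ECG and spike artifacts into subcortical channels
#'
#' Adds jittered QRS-shaped cardiac transients and sparse large raised-cosine
#' spikes to the subcortical channels only, returning the exact injected
#' event times/intervals as ground truth.
#'
#' @param rec clean [new_recording()].
#' @param cfg a [synth_config()].
#' @param seed RNG seed for artifact placement.
#' @return list(`recording`, `truth`) where truth has `ecg_event_times` (s,
#'   QRS onsets) and `spike_intervals` (data.frame start_s/stop_s).
#' @export
inject_artifacts <- function(rec, cfg, seed = cfg$seed + 2L) {
  stopifnot(inherits(rec, "fp_recording"))
  fs <- rec$fs
  n <- ncol(rec$samples)
  sub_idx <- which(rec$channels$region == "subcortex")
  with_seed(seed, {
    x <- rec$samples
    ecg_times <- numeric(0)
    if (cfg$ecg$amp_uv > 0 && length(sub_idx)) {
      qrs <- .qrs_shape(fs, cfg$ecg$qrs_width_s) * cfg$ecg$amp_uv
      ibi <- 60 / cfg$ecg$rate_bpm
      t <- stats::runif(1, 0, ibi)
      while (t < n / fs - cfg$ecg$qrs_width_s) {
        ecg_times <- c(ecg_times, t)
        t <- t + ibi * (1 + stats::runif(1, -0.1, 0.1))
      }
      side_gain <- stats::runif(length(sub_idx), 0.8, 1.2)
      for (k in seq_along(sub_idx)) {
        for (tt in ecg_times) {
          i0 <- round(tt * fs) + 1L
          ii <- i0:(i0 + length(qrs) - 1L)
          keep <- ii <= n
          x[sub_idx[k], ii[keep]] <- x[sub_idx[k], ii[keep]] +
            side_gain[k] * qrs[keep]
        }
      }
    }
    spikes <- data.frame(start_s = numeric(0), stop_s = numeric(0))
    if (cfg$spikes$amp_uv > 0 && length(sub_idx)) {
      n_sp <- stats::rpois(1, cfg$spikes$rate_per_hr * n / fs / 3600)
      if (n_sp > 0) {
        st <- sort(stats::runif(n_sp, 0, n / fs - 1))
        dur <- stats::runif(n_sp, 0.15, 0.4)
        amp <- cfg$spikes$amp_uv * stats::runif(n_sp, 0.6, 1.2)
        for (k in seq_len(n_sp)) {
          i0 <- round(st[k] * fs) + 1L
          m <- round(dur[k] * fs)
          ii <- i0:min(i0 + m - 1L, n)
          bump <- amp[k] * (0.5 - 0.5 * cos(2 * pi * seq_along(ii) /
                                              length(ii)))
          for (s in sub_idx) x[s, ii] <- x[s, ii] + bump
        }
        spikes <- data.frame(start_s = st, stop_s = st + dur)
      }
    }
    rec$samples <- x
    list(recording = rec,
         truth = list(ecg_event_times = ecg_times, spike_intervals = spikes))
  })
}

#' Synthesize a lagged implant/headband accelerometer pair
#'
#' Both devices observe the same movement process (noise bursts during wake
#' plus five sharp synchronization taps near the start of the night); the
#' headband copy is delayed by `accel_lag_s` and carries independent sensor
#' noise. The implant samples at 64 Hz, the headband at 50 Hz.
#'
#' @param h hypnogram (wake periods gate the movement bursts).
#' @param cfg a [synth_config()].
#' @return list(`implant`, `headband`) of [new_accel()] traces.
#' @export
synthesize_accel_pair <- function(h, cfg) {
  stopifnot(inherits(h, "hypnogram"))
  fine <- expand_stages(h)
  dur <- length(fine) * 5
  master_fs <- 200
  with_seed(cfg$seed + 3L, {
    nm <- dur * master_fs
    move <- .movavg(stats::rnorm(nm), master_fs %/% 4)
    gate <- .movavg(rep(as.numeric(fine == "W"), each = 5 * master_fs),
                    2 * master_fs)
    s <- 0.5 * move / stats::sd(move) * gate
    tap_t <- 10 + 2 * (0:4)
    for (tt in tap_t) {
      ii <- round(tt * master_fs) + seq_len(master_fs %/% 10)
      s[ii] <- s[ii] + 2 * sin(2 * pi * seq_along(ii) / length(ii))
    }
    tm <- (seq_len(nm) - 1) / master_fs
    w <- abs(stats::rnorm(3)); w <- w / sqrt(sum(w^2))
    sample_at <- function(fs_dev, lag, noise_sd) {
      td <- seq(0, dur - 1 / fs_dev, by = 1 / fs_dev)
      base <- stats::approx(tm, s, xout = td - lag, rule = 2)$y
      xyz <- rbind(w[1] * base, w[2] * base, w[3] * base + 1)  # gravity on z
      xyz + matrix(stats::rnorm(3 * length(td), sd = noise_sd), nrow = 3)
    }
    list(implant = new_accel(sample_at(64, 0, 0.02), 64, "implant"),
         headband = new_accel(sample_at(50, cfg$accel_lag_s, 0.02), 50,
                              "headband"))
  })
}

#' Generate a complete synthetic night
#'
#' Composes [generate_hypnogram()], [synthesize_clean_fp()],
#' [inject_artifacts()] and [synthesize_accel_pair()] into one reproducible
#' night with full ground truth.
#'
#' @param cfg a [synth_config()].
#' @return list of class `synth_night`: `recording` (with artifacts),
#'   `clean_recording`, `hypnogram`, `accel_pair`, `truth`.
#' @export
generate_night <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  h <- generate_hypnogram(cfg)
  clean <- synthesize_clean_fp(h, cfg)
  art <- inject_artifacts(clean, cfg)
  acc <- synthesize_accel_pair(h, cfg)
  structure(list(
    recording = art$recording,
    clean_recording = clean,
    hypnogram = h,
    accel_pair = acc,
    truth = c(art$truth,
              list(coupling_lag_s = cfg$coupling_lag_s,
                   coupling_gain = cfg$coupling_gain,
                   prewake_ramp = cfg$prewake_ramp,
                   accel_lag_s = cfg$accel_lag_s))),
    class = "synth_night")
}

#' Write a synthetic night to disk
#'
#' EDF signals, hypnogram and fine-label CSVs, and a truth JSON.
#'
#' @param night a [generate_night()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_night <- function(night, dir) {
  stopifnot(inherits(night, "synth_night"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_recording_edf(night$recording, file.path(dir, "fp.edf"))
  write_hypnogram(night$hypnogram, file.path(dir, "hypnogram.csv"),
                  file.path(dir, "hypnogram_fine.csv"))
  tr <- night$truth
  tr$spike_intervals <- as.list(tr$spike_intervals)
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
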