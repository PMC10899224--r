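# Shared fixtures: short-night configurations (compressed pre-sleep wake so
# half-hour nights still contain sleep cycles) and a lazy night cache so
# expensive simulated nights are generated once per test run.

short_dwell <- list(W_start = 120, N1 = 90, N2 = 210, N3 = 270,
                    R = 540, W = 120)

test_cfg <- function(seed, dur = 1800, ...) {
  synth_config(seed = seed, night_dur_s = dur,
               stage_dwell_means_s = short_dwell, ...)
}

# transition-rich profile: fast NREM cycling with awakenings long enough to
# pass the 25 s validity bar gives a 40 min night one-to-two valid
# N2/N3-to-wake events
trans_dwell <- list(W_start = 60, N1 = 90, N2 = 180, N3 = 210,
                    R = 300, W = 120)

trans_cfg <- function(seed, gain = 1, dur = 2400) {
  synth_config(seed = seed, night_dur_s = dur,
               stage_dwell_means_s = trans_dwell,
               prewake_ramp = list(lead_s = 10, gain = gain))
}

# per-event (-7.5 s bin - deep NREM) and (+12.5 s bin - deep NREM)
# contrasts for one synthetic night, one region/band
night_transition_contrasts <- function(cfg, region = "subcortex",
                                       band = c(13, 31)) {
  n <- cached_night(cfg)
  rec <- n$clean_recording
  ci <- which(rec$channels$region == region)[1]
  x <- rec$samples[ci, ]
  x <- (x - mean(x)) / sd(x)
  env <- hilbert_band_power(x, rec$fs, band)
  ev <- find_transitions(n$hypnogram)
  if (sum(ev$valid) == 0) return(NULL)
  transition_contrasts(timelock_transitions(env, rec$fs, ev))
}

.night_cache <- new.env(parent = emptyenv())
.night_cache$order <- character(0)
.night_cache$max_nights <- 6L       # bounded: a night is tens of MB

cached_night <- function(cfg) {
  key <- paste0("n_", digest_cfg(cfg))
  if (is.null(.night_cache[[key]])) {
    .night_cache[[key]] <- generate_night(cfg)
    .night_cache$order <- c(.night_cache$order, key)
    while (length(.night_cache$order) > .night_cache$max_nights) {
      rm(list = .night_cache$order[1], envir = .night_cache)
      .night_cache$order <- .night_cache$order[-1]
    }
  }
  .night_cache[[key]]
}

digest_cfg <- function(cfg) {
  paste(cfg$seed, cfg$night_dur_s, cfg$coupling_gain, cfg$coupling_lag_s,
        cfg$prewake_ramp$gain, cfg$ecg$amp_uv, cfg$spikes$amp_uv,
        cfg$accel_lag_s, paste(unlist(cfg$stage_dwell_means_s),
                               collapse = "."), sep = "_")
}

# The transition study: paired nights sharing a seed, one with the
# pre-awakening beta ramp injected and one with the ramp gain set to zero.
# A shared seed makes every other source of variation (hypnogram, carriers,
# coupling driver, background) bit-identical, so per-event paired
# differences isolate the ramp. Only small derived products are kept: the
# per-event contrasts of both arms and, for the first `n_feat` nights per
# arm, subcortical 5 s ML feature tables split into a training pool and
# held-out peri-transition epochs. Computed lazily once per test run.
.trans_study <- new.env(parent = emptyenv())

transition_study <- function(seeds = 1301:1325, n_feat = 16) {
  if (!is.null(.trans_study$res)) return(.trans_study$res)
  one_arm_night <- function(s, gain, want_features) {
    n <- generate_night(trans_cfg(s, gain = gain))
    rec <- n$clean_recording
    ev <- find_transitions(n$hypnogram)
    if (sum(ev$valid) == 0) return(NULL)
    zch <- function(i) {
      v <- rec$samples[i, ]; (v - mean(v)) / sd(v)
    }
    si <- which(rec$channels$region == "subcortex")[1]
    ci <- which(rec$channels$region == "cortex")[1]
    eb <- hilbert_band_power(zch(si), rec$fs, c(13, 31))
    beta <- transition_contrasts(timelock_transitions(eb, rec$fs, ev))
    ed <- hilbert_band_power(zch(ci), rec$fs, c(1, 4))
    delta <- transition_contrasts(timelock_transitions(ed, rec$fs, ev))
    out <- list(beta = beta, delta = delta)
    if (want_features) {
      b <- epoch_band_powers(rec, n$hypnogram, epoch_len_s = 5,
                             scheme = "ml")
      b <- b[b$region == "subcortex", ]
      spl <- build_transition_features(b, ev)
      out$train_pool <- spl$train_pool
      out$transition_ft <- spl$transition_ft
    }
    out
  }
  ramp <- list(); null_ <- list()
  for (s in seeds) {
    want <- length(ramp) < n_feat
    r <- one_arm_night(s, 1, want)
    z <- one_arm_night(s, 0, want)
    # the hypnogram is seed-determined, so arms have identical event sets
    if (is.null(r) || is.null(z)) next
    ramp[[length(ramp) + 1L]] <- r
    null_[[length(null_) + 1L]] <- z
  }
  gather <- function(arm, what)
    do.call(rbind, Filter(Negate(is.null), lapply(arm, `[[`, what)))
  .trans_study$res <- list(
    ramp = list(beta = gather(ramp, "beta"), delta = gather(ramp, "delta"),
                train_pool = gather(ramp, "train_pool"),
                transition_ft = gather(ramp, "transition_ft")),
    null = list(beta = gather(null_, "beta"),
                delta = gather(null_, "delta"),
                train_pool = gather(null_, "train_pool"),
                transition_ft = gather(null_, "transition_ft")),
    n_nights = length(ramp))
  .trans_study$res
}

# epoch-level mixed-model simulation: participants x nights x epochs with
# random intercepts at both levels
simulate_lme_data <- function(seed, slope = 0, n_part = 6, n_night = 3,
                              n_epoch = 20, sd_part = 0.6, sd_night = 0.4) {
  set.seed(seed)
  d <- expand.grid(participant_id = paste0("P", seq_len(n_part)),
                   night_id = paste0("n", seq_len(n_night)),
                   ep = seq_len(n_epoch))
  d$x <- rnorm(nrow(d))
  u_p <- rnorm(n_part, sd = sd_part)
  u_n <- rnorm(n_part * n_night, sd = sd_night)
  d$y <- slope * d$x + u_p[as.integer(d$participant_id)] +
    u_n[as.integer(interaction(d$participant_id, d$night_id))] +
    rnorm(nrow(d))
  d
}

# three-axis accelerometer fixture built from a shared smooth movement
# process, with optional delay and independent per-device noise
make_accel_pair <- function(seed, dur_s = 120, lag_s = 0, fs_a = 64,
                            fs_b = 50, noise_sd = 0.02, shared = TRUE) {
  set.seed(seed)
  master_fs <- 200
  n <- dur_s * master_fs
  s <- stats::filter(rnorm(n), rep(1 / 50, 50), circular = TRUE)
  s <- as.numeric(s) / sd(s)
  tm <- (seq_len(n) - 1) / master_fs
  samp <- function(fs_dev, lag, own) {
    td <- seq(0, dur_s - 1 / fs_dev, by = 1 / fs_dev)
    base <- if (shared) approx(tm, s, xout = td - lag, rule = 2)$y
      else { set.seed(seed + own); filt <- rnorm(length(td)); filt / sd(filt) }
    rbind(base, 0.5 * base, 0.2 * base + 1) +
      matrix(rnorm(3 * length(td), sd = noise_sd), nrow = 3)
  }
  list(a = new_accel(samp(fs_a, 0, 1), fs_a, "implant"),
       b = new_accel(samp(fs_b, lag_s, 2), fs_b, "headband"))
}
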