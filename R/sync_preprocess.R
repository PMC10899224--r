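## Stream synchronization, signal conditioning, artifactual-spike excision and
## hybrid ECG template subtraction (seeded template + Woody adaptive filter
## with an acceptance gate and forced searches).

#' Estimate the inter-device clock lag from paired accelerometry
#'
#' Both traces are resampled to a common rate, reduced to their Euclidean
#' norm across axes, and the lag maximizing the normalized cross-correlation
#' within `+/- max_lag_s` is returned. Positive lag means `b` (headband) is
#' delayed relative to `a` (implant). The estimate is flagged confident when
#' the correlation peak reaches 0.5; low peaks indicate the two streams do
#' not share movement structure.
#'
#' @param a,b [new_accel()] traces (implant, headband).
#' @param common_fs common resampling rate, Hz.
#' @param max_lag_s maximum absolute lag searched, seconds.
#' @return list(`lag_s`, `peak_ncc`, `confident`) of class `sync_result`.
#' @export
estimate_lag <- function(a, b, common_fs = 50, max_lag_s = 10) {
  stopifnot(inherits(a, "accel_trace"), inherits(b, "accel_trace"))
  dur <- min(ncol(a$xyz) / a$fs, ncol(b$xyz) / b$fs)
  if (dur < 10 * max_lag_s)
    stop("insufficient overlap: need at least 10 x max_lag_s of shared data")
  res <- function(tr) {
    ax <- apply(tr$xyz, 1, .resample_lin, fs = tr$fs, target_fs = common_fs)
    sqrt(rowSums(ax^2))
  }
  na <- res(a); nb <- res(b)
  n <- min(length(na), length(nb))
  xc <- norm_xcorr(na[seq_len(n)], nb[seq_len(n)],
                   max_lag = round(max_lag_s * common_fs))
  i <- which.max(xc$ncc)
  structure(list(lag_s = xc$lags[i] / common_fs, peak_ncc = xc$ncc[i],
                 confident = xc$ncc[i] >= 0.5),
            class = "sync_result")
}

#' Condition a recording: resample and zero-phase elliptic bandpass
#'
#' Anti-aliased resampling to `target_fs` followed by a forward-backward
#' (zero-phase) IIR elliptic bandpass, 0.8-100 Hz, 1 dB passband ripple and
#' 100 dB stopband attenuation, implemented as a high-pass/low-pass cascade.
#' Optionally z-scores each channel over the night (required before spectral
#' estimation).
#'
#' @param rec an [new_recording()].
#' @param target_fs target sampling rate, Hz.
#' @param band passband edges in Hz.
#' @param zscore z-score each channel after filtering.
#' @return conditioned [new_recording()].
#' @export
condition_signal <- function(rec, target_fs = 250, band = c(0.8, 100),
                             zscore = FALSE) {
  stopifnot(inherits(rec, "fp_recording"))
  if (!rec$fs %in% c(250, 500))
    warning("unexpected sampling rate ", rec$fs, " Hz; resampling anyway")
  if (target_fs < 2 * band[2])
    stop("design error: target_fs below twice the upper passband edge")
  x <- rec$samples
  if (rec$fs != target_fs) {
    if (rec$fs > target_fs) {
      aa <- signal::butter(8, 0.9 * (target_fs / 2) / (rec$fs / 2), "low")
      x <- t(apply(x, 1, function(ch) signal::filtfilt(aa, ch)))
    }
    x <- t(apply(x, 1, .resample_lin, fs = rec$fs, target_fs = target_fs))
  }
  flt <- .ellip_bandpass(target_fs, band)
  x <- t(apply(x, 1, function(ch) {
    ch <- signal::filtfilt(flt$hp, ch)
    signal::filtfilt(flt$lp, ch)
  }))
  if (zscore) x <- t(apply(x, 1, function(ch) (ch - mean(ch)) / stats::sd(ch)))
  out <- rec
  out$samples <- x
  out$fs <- target_fs
  out
}

## Elliptic single-sided design by order probing: smallest order (<= 7, to
## stay numerically stable in transfer-function form at extreme corner
## ratios) whose designed response meets the stopband attenuation at the
## stopband edge and whose poles are strictly inside the unit circle.
.ellip_side <- function(fs, corner, type, rp, rs, stop_edge) {
  nyq <- fs / 2
  best <- NULL; best_att <- -Inf
  for (n in 3:7) {
    f <- signal::ellip(n, rp, rs, corner / nyq, type = type)
    if (any(Mod(polyroot(rev(f$a))) >= 1 - 1e-8)) next
    h <- signal::freqz(f, Fs = fs, n = 4096)
    att <- -20 * log10(Mod(h$h[which.min(abs(h$f - stop_edge))]) + 1e-300)
    if (att > best_att) { best <- f; best_att <- att }
    if (att >= rs) break
  }
  best
}

## Zero-phase elliptic bandpass as a high-pass/low-pass cascade with the
## stated ripple/attenuation; transition bands one octave below the low
## corner and 10% above the high corner.
.ellip_bandpass <- function(fs, band = c(0.8, 100), rp = 1, rs = 100) {
  list(hp = .ellip_side(fs, band[1], "high", rp, rs,
                        stop_edge = band[1] / 4),
       lp = .ellip_side(fs, band[2], "low", rp, rs,
                        stop_edge = min(1.1 * band[2], 0.99 * fs / 2)))
}

## ---------------------------------------------------------------------------
## Artifactual spike excision

.intervals_from_logical <- function(m, fs) {
  r <- rle(m)
  stops <- cumsum(r$lengths)
  starts <- c(0L, stops[-length(stops)])
  keep <- r$values
  data.frame(start_s = starts[keep] / fs, stop_s = stops[keep] / fs)
}

.merge_intervals <- function(iv) {
  if (nrow(iv) < 2) return(iv)
  iv <- iv[order(iv$start_s), ]
  out <- iv[1, ]
  for (k in 2:nrow(iv)) {
    if (iv$start_s[k] <= out$stop_s[nrow(out)])
      out$stop_s[nrow(out)] <- max(out$stop_s[nrow(out)], iv$stop_s[k])
    else out <- rbind(out, iv[k, ])
  }
  rownames(out) <- NULL
  out
}

#' Per-sample logical view of an artifact mask
#'
#' @param mask an `artifact_mask` from [detect_and_excise_spikes()].
#' @param n number of samples.
#' @param fs sampling rate, Hz.
#' @return logical vector, `TRUE` inside masked intervals.
#' @export
mask_logical <- function(mask, n, fs) {
  m <- logical(n)
  if (nrow(mask$intervals))
    for (k in seq_len(nrow(mask$intervals))) {
      i0 <- max(1L, floor(mask$intervals$start_s[k] * fs) + 1L)
      i1 <- min(n, ceiling(mask$intervals$stop_s[k] * fs))
      if (i1 >= i0) m[i0:i1] <- TRUE
    }
  m
}

#' Detect and excise large artifactual spikes
#'
#' The absolute squared subcortical signal is smoothed with a Gaussian kernel
#' of 1 s total support; any period exceeding 5 times the whole-night median
#' of the smoothed power is flagged as an artifactual spike. Flagged periods
#' (with guard padding) are zeroed in BOTH the subcortical channel and its
#' paired cortical channel, and returned as a mask so that epoch bookkeeping
#' can skip contaminated epochs.
#'
#' @param subcort,paired_cort equal-length signal vectors.
#' @param fs sampling rate, Hz.
#' @param threshold_mult multiple of the whole-night median.
#' @param kernel_support_s Gaussian kernel total support, seconds.
#' @param guard_s guard padding added on each side of a detection, seconds.
#' @return list(`subcort`, `cort`, `mask`) where `mask` is an
#'   `artifact_mask` (sorted, non-overlapping `intervals`).
#' @export
detect_and_excise_spikes <- function(subcort, paired_cort, fs,
                                     threshold_mult = 5,
                                     kernel_support_s = 1, guard_s = 0.5) {
  if (length(subcort) != length(paired_cort))
    stop("paired channels must have equal length")
  sm <- gaussian_smooth(subcort^2, round(kernel_support_s * fs))
  med <- stats::median(sm)
  mask <- structure(list(intervals = data.frame(start_s = numeric(0),
                                                stop_s = numeric(0))),
                    class = "artifact_mask")
  if (med > 0) {
    iv <- .intervals_from_logical(sm > threshold_mult * med, fs)
    if (nrow(iv)) {
      iv$start_s <- pmax(0, iv$start_s - guard_s)
      iv$stop_s <- pmin(length(subcort) / fs, iv$stop_s + guard_s)
      mask$intervals <- .merge_intervals(iv)
    }
  }
  m <- mask_logical(mask, length(subcort), fs)
  subcort[m] <- 0
  paired_cort[m] <- 0
  list(subcort = subcort, cort = paired_cort, mask = mask)
}

## ---------------------------------------------------------------------------
## ECG template subtraction

new_ecg_template <- function(waveform, origin = c("seed", "refined"),
                             max_ncc_vs_seed = NA_real_, accepted = NA) {
  origin <- match.arg(origin)
  e <- sqrt(sum(waveform^2))
  if (e == 0) stop("degenerate zero-energy template")
  structure(list(waveform = waveform / e, origin = origin,
                 max_ncc_vs_seed = max_ncc_vs_seed, accepted = accepted),
            class = "ecg_template")
}

#' Maximum normalized cross-correlation between two short waveforms
#'
#' Alignment-tolerant similarity used by the template acceptance gate: the
#' maximum over all shifts of the normalized inner product.
#'
#' @param a,b numeric waveforms.
#' @return scalar in `[-1, 1]`.
#' @export
template_max_ncc <- function(a, b) {
  la <- length(a); lb <- length(b)
  n <- la + lb
  xc <- norm_xcorr(c(a - mean(a), rep(0, n - la)),
                   c(b - mean(b), rep(0, n - lb)),
                   max_lag = n - 1, demean = FALSE)
  max(xc$ncc)
}

#' Acceptance gate for a refined ECG template
#'
#' A template refined by the adaptive filter is accepted only if its maximum
#' normalized cross-correlation with the initial seed reaches the
#' predetermined threshold of 0.9; otherwise the refinement is rejected
#' (guarding against the template locking onto low-frequency rhythmic neural
#' activity) and removal falls back to forced searches with the fixed seed.
#'
#' @param refined,seed numeric waveforms (refined template, seed template).
#' @param threshold acceptance threshold on the maximum NCC.
#' @return list(`accepted`, `max_ncc`).
#' @export
accept_template <- function(refined, seed, threshold = 0.9) {
  ncc <- template_max_ncc(refined, seed)
  list(accepted = ncc >= threshold, max_ncc = ncc)
}

## Sliding normalized cross-correlation of a unit-energy template against a
## signal; returns vector over start positions 1..n-L+1.
.sliding_ncc <- function(x, tmpl) {
  L <- length(tmpl)
  n <- length(x)
  # FFT correlation on a highly composite padded length
  m <- stats::nextn(n + L - 1L, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, m - n)))
  Tm <- stats::fft(c(rev(tmpl), rep(0, m - L)))
  full <- Re(stats::fft(X * Tm, inverse = TRUE)) / m
  num <- full[L:(n)]                                      # length n-L+1
  cs2 <- cumsum(c(0, x^2))
  e <- cs2[(L + 1):(n + 1)] - cs2[1:(n - L + 1)]
  num / sqrt(pmax(e, 1e-12)) / sqrt(sum(tmpl^2))
}

## Local maxima of v above thr with a refractory spacing (keep higher peaks).
.pick_events <- function(v, thr, refractory_n) {
  n <- length(v)
  if (n < 3) return(integer(0))
  core <- v[2:(n - 1)]
  cand <- which(core >= thr & core >= v[1:(n - 2)] & core >= v[3:n]) + 1L
  cand <- cand[order(v[cand], decreasing = TRUE)]
  blocked <- logical(n)
  taken <- integer(0)
  for (i in cand) {
    if (blocked[i]) next
    taken <- c(taken, i)
    blocked[max(1L, i - refractory_n + 1L):min(n, i + refractory_n - 1L)] <-
      TRUE
  }
  sort(taken)
}

#' Build a per-night seed ECG template from sharp QRS-like deflections
#'
#' For each 10 min non-overlapping window (a trailing partial window is
#' appended to the last full one), candidate QRS events are peak-detected
#' (prominence above `peak_mult` robust SDs, physiological inter-beat spacing
#' 0.4-2.0 s), aligned on their dominant deflection and averaged into a
#' window template. Windows without a plausible beat train contribute
#' nothing; if no window yields candidates the function returns `NULL` and
#' the caller skips ECG removal. Window templates are averaged into the
#' per-night seed.
#'
#' @param x subcortical signal vector.
#' @param fs sampling rate, Hz.
#' @param window_s window length, seconds.
#' @param peak_mult detection threshold in robust (MAD) SD units.
#' @param half_width_s template half-width around the aligned peak, seconds.
#' @return list(`seed` = `ecg_template`, `window_templates` = list) or
#'   `NULL`.
#' @export
build_seed_template <- function(x, fs, window_s = 600, peak_mult = 3.5,
                                half_width_s = 0.1) {
  n <- length(x)
  if (n < window_s * fs) window_s <- n / fs
  n_win <- max(1L, floor(n / (window_s * fs)))
  bounds <- round(seq(0, by = window_s * fs, length.out = n_win + 1L))
  bounds[n_win + 1L] <- n                      # trailing partial -> last window
  hw <- round(half_width_s * fs)
  # peak detection runs on a 5-45 Hz bandpassed copy (the energy band of
  # sharp QRS-like deflections), suppressing slow-wave background; snippets
  # are extracted from the raw signal
  bp <- signal::butter(3, c(5, 45) / (fs / 2), type = "pass")
  xd <- signal::filtfilt(bp, x)
  win_templates <- list()
  for (w in seq_len(n_win)) {
    seg <- x[(bounds[w] + 1L):bounds[w + 1L]]
    det <- xd[(bounds[w] + 1L):bounds[w + 1L]]
    sdr <- stats::mad(det)
    if (sdr == 0) next
    pk <- .pick_events(abs(det), peak_mult * sdr, round(0.4 * fs))
    pk <- pk[pk > hw & pk <= length(seg) - hw]
    if (length(pk) < 0.4 * window_s) next      # below a 24 bpm beat train
    ibi <- diff(pk) / fs
    if (mean(ibi >= 0.4 & ibi <= 2.0) < 0.7) next
    snip <- vapply(pk, function(p) {
      s <- seg[(p - hw):(p + hw)]
      s * sign(seg[p])                         # align dominant deflection up
    }, numeric(2L * hw + 1L))
    win_templates[[length(win_templates) + 1L]] <- rowMeans(snip)
  }
  if (!length(win_templates)) return(NULL)
  avg <- Reduce(`+`, win_templates) / length(win_templates)
  list(seed = new_ecg_template(avg, origin = "seed"),
       window_templates = win_templates)
}

#' Remove ECG artifacts by seeded adaptive template subtraction
#'
#' Applied separately to each 10 min non-overlapping window with the same
#' initial seed. In each window a Woody adaptive loop cross-correlates the
#' template with the signal, picks events above the match threshold with a
#' refractory spacing, re-averages the aligned events into an updated
#' template and iterates to convergence. The refined template passes through
#' [accept_template()]: if its maximum NCC against the seed is below 0.9 the
#' refinement is discarded and detection is redone with the fixed seed
#' template. A forced-search pass then scans gaps in the detected beat train
#' (at a lowered threshold) for events the adaptive stage missed. Each event
#' is removed by subtracting the least-squares-scaled template.
#'
#' @param x subcortical signal vector.
#' @param fs sampling rate, Hz.
#' @param seed an `ecg_template` from [build_seed_template()].
#' @param window_s processing window, seconds.
#' @param match_thr adaptive-stage event threshold (NCC).
#' @param forced_thr forced-search threshold (NCC).
#' @param refractory_s minimum event spacing, seconds.
#' @param gate_threshold acceptance-gate NCC threshold against the seed.
#' @param max_iter,tol Woody loop limits (iterations, RMS template change).
#' @return list(`cleaned`, `template` = final `ecg_template` of the last
#'   window, `event_times` in seconds).
#' @export
remove_ecg <- function(x, fs, seed, window_s = 600, match_thr = 0.6,
                       forced_thr = 0.4, refractory_s = 0.4,
                       gate_threshold = 0.9, max_iter = 10, tol = 1e-3) {
  stopifnot(inherits(seed, "ecg_template"))
  n <- length(x)
  if (n < window_s * fs) window_s <- n / fs
  n_win <- max(1L, floor(n / (window_s * fs)))
  bounds <- round(seq(0, by = window_s * fs, length.out = n_win + 1L))
  bounds[n_win + 1L] <- n
  refr <- round(refractory_s * fs)
  L <- length(seed$waveform)
  all_events <- numeric(0)
  final_tmpl <- seed
  # a credible cardiac beat train: at least ~18 bpm worth of events whose
  # inter-beat spacing is mostly physiological; windows without one are
  # left untouched (no artifact present)
  credible <- function(ev, seg_s) {
    if (length(ev) < max(5, 0.3 * seg_s)) return(FALSE)
    ibi <- diff(ev) / fs
    med <- stats::median(ibi)
    # cardiac trains are quasi-periodic: most intervals sit near the median
    # (occasional missed beats give multiples); noise matches do not
    med >= 0.4 && med <= 2.0 && mean(abs(ibi / med - 1) <= 0.25) >= 0.6
  }
  for (w in seq_len(n_win)) {
    i0 <- bounds[w] + 1L
    seg <- x[i0:bounds[w + 1L]]
    seg_s <- length(seg) / fs
    if (length(seg) <= L) next
    tmpl <- seed$waveform
    ev <- integer(0)
    for (it in seq_len(max_iter)) {
      ncc <- .sliding_ncc(seg, tmpl)
      ev <- .pick_events(ncc, match_thr, refr)
      if (length(ev) < 5) break
      snip <- vapply(ev, function(p) seg[p:(p + L - 1L)], numeric(L))
      new <- rowMeans(snip)
      e <- sqrt(sum(new^2))
      if (e == 0) break
      new <- new / e
      delta <- sqrt(mean((new - tmpl)^2))
      tmpl <- new
      if (delta < tol) break
    }
    if (!credible(ev, seg_s)) next         # nothing to remove in this window
    gate <- accept_template(tmpl, seed$waveform, gate_threshold)
    if (!gate$accepted) {
      # refinement rejected: forced search with the fixed seed template,
      # no recursive update
      tmpl <- seed$waveform
      ncc <- .sliding_ncc(seg, tmpl)
      ev <- .pick_events(ncc, forced_thr, refr)
      if (!credible(ev, seg_s)) next
      final_tmpl <- new_ecg_template(tmpl, "seed",
                                     max_ncc_vs_seed = gate$max_ncc,
                                     accepted = FALSE)
    } else {
      final_tmpl <- new_ecg_template(tmpl, "refined",
                                     max_ncc_vs_seed = gate$max_ncc,
                                     accepted = TRUE)
      # forced search in gaps of the detected beat train
      ncc <- .sliding_ncc(seg, tmpl)
      ibi <- stats::median(diff(ev))
      gaps <- which(diff(ev) > 1.5 * ibi)
      for (g in gaps) {
        lo <- ev[g] + refr; hi <- ev[g + 1L] - refr
        if (hi <= lo) next
        sub <- ncc[lo:hi]
        extra <- .pick_events(sub, forced_thr, refr) + lo - 1L
        ev <- c(ev, extra)
      }
      ev <- sort(unique(ev))
    }
    # subtract least-squares-scaled template at each event
    for (p in ev) {
      idx <- p:(p + L - 1L)
      a <- sum(seg[idx] * tmpl)
      seg[idx] <- seg[idx] - a * tmpl
    }
    x[i0:bounds[w + 1L]] <- seg
    all_events <- c(all_events, (ev - 1L + i0 - 1L) / fs)
  }
  list(cleaned = x, template = final_tmpl, event_times = sort(all_events))
}

#' Preprocess a full night end to end
#'
#' Conditions the recording, excises spikes per hemisphere (subcortical
#' channel paired with the same-hemisphere cortical channel) and removes ECG
#' artifacts from the subcortical channels via the seeded adaptive template
#' pipeline.
#'
#' @param rec raw [new_recording()].
#' @param target_fs conditioning target rate, Hz.
#' @param zscore z-score channels after cleaning.
#' @param ecg_removal run the ECG template-subtraction stage.
#' @return list(`recording`, `masks` per hemisphere, `ecg` per subcortical
#'   channel).
#' @export
preprocess_night <- function(rec, target_fs = 250, zscore = TRUE,
                             ecg_removal = TRUE) {
  rec <- condition_signal(rec, target_fs = target_fs, zscore = FALSE)
  ch <- rec$channels
  masks <- list(); ecg <- list()
  for (hem in unique(ch$hemisphere)) {
    si <- which(ch$region == "subcortex" & ch$hemisphere == hem)
    ci <- which(ch$region == "cortex" & ch$hemisphere == hem)
    if (!length(si) || !length(ci)) next
    sp <- detect_and_excise_spikes(rec$samples[si, ], rec$samples[ci, ],
                                   rec$fs)
    rec$samples[si, ] <- sp$subcort
    rec$samples[ci, ] <- sp$cort
    masks[[hem]] <- sp$mask
    if (ecg_removal) {
      st <- build_seed_template(rec$samples[si, ], rec$fs)
      if (!is.null(st)) {
        rm_ <- remove_ecg(rec$samples[si, ], rec$fs, st$seed)
        rec$samples[si, ] <- rm_$cleaned
        ecg[[ch$label[si]]] <- rm_[c("template", "event_times")]
      }
    }
  }
  if (zscore)
    rec$samples <- t(apply(rec$samples, 1,
                           function(x) (x - mean(x)) / stats::sd(x)))
  list(recording = rec, masks = masks, ecg = ecg)
}
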