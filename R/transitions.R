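## NREM-to-wake transition detection and transition-locked band-power
## dynamics around spontaneous awakenings.

#' Detect N2/N3 NREM to wake transitions
#'
#' Every maximal N2/N3 run immediately followed by wake yields an event; an
#' event is valid when the NREM run lasted at least 85 s and the following
#' wake period at least 25 s. Uses the 5 s fine re-scored track when present
#' (precise awakening times), else the 30 s labels.
#'
#' @param h a [new_hypnogram()].
#' @param use_fine use `fine_stages` when available.
#' @param min_nrem_s,min_wake_s validity thresholds, seconds.
#' @return data.frame: `nrem_onset_s`, `wake_onset_s`, `nrem_dur_s`,
#'   `wake_dur_s`, `valid`.
#' @export
find_transitions <- function(h, use_fine = TRUE,
                             min_nrem_s = 85, min_wake_s = 25) {
  stopifnot(inherits(h, "hypnogram"))
  if (use_fine && !is.null(h$fine_stages)) {
    lab <- h$fine_stages; res <- 5
  } else {
    lab <- h$stages; res <- h$epoch_len_s
  }
  grp <- ifelse(lab %in% c("N2", "N3"), "NREM", lab)
  r <- rle(grp)
  stops <- cumsum(r$lengths); starts <- c(0L, stops[-length(stops)])
  idx <- which(r$values == "NREM")
  idx <- idx[idx < length(r$values) & r$values[pmin(idx + 1L,
                                                    length(r$values))] == "W"]
  if (!length(idx))
    return(data.frame(nrem_onset_s = numeric(0), wake_onset_s = numeric(0),
                      nrem_dur_s = numeric(0), wake_dur_s = numeric(0),
                      valid = logical(0)))
  ev <- data.frame(
    nrem_onset_s = starts[idx] * res,
    wake_onset_s = stops[idx] * res,
    nrem_dur_s = r$lengths[idx] * res,
    wake_dur_s = r$lengths[idx + 1L] * res)
  ev$valid <- ev$nrem_dur_s >= min_nrem_s & ev$wake_dur_s >= min_wake_s
  ev
}

#' Band-specific Hilbert envelope power in dB
#'
#' Zero-phase elliptic bandpass to the requested band, analytic-signal
#' magnitude squared, converted to decibels. The input should be z-scored
#' per night.
#'
#' @param x z-scored signal vector.
#' @param fs sampling rate, Hz.
#' @param band `c(f_lo, f_hi)` in Hz, within `(0, fs/2)`.
#' @return dB envelope series, same length as `x`.
#' @export
hilbert_band_power <- function(x, fs, band) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fs / 2)
    stop("band must be within (0, fs/2)")
  flt <- .ellip_bandpass(fs, band, rp = 1, rs = 60)
  x <- signal::filtfilt(flt$hp, x)
  x <- signal::filtfilt(flt$lp, x)
  env2 <- Mod(analytic_signal(x))^2
  10 * log10(pmax(env2, 1e-300))
}

#' Time-lock an envelope to awakening events
#'
#' Averages the dB envelope into 5 s epochs on a grid anchored at each
#' event's wake onset (bins `[-5, 0) -> -2.5 s`, `[0, 5) -> +2.5 s`, ...)
#' spanning from the NREM onset to the wake end. Also computes the per-event
#' deep-NREM summary (epochs from 40 s after NREM onset to 40 s before
#' awakening) and awake summary (epochs from 25 s after wake onset to wake
#' end). Events not fully covered by the signal are dropped with a warning;
#' events overlapping artifact-masked intervals by more than 20% of their
#' span are dropped too.
#'
#' @param env_db dB envelope series from [hilbert_band_power()].
#' @param fs sampling rate, Hz.
#' @param events valid rows of [find_transitions()].
#' @param epoch_len_s relative-grid epoch length, seconds.
#' @param mask optional `artifact_mask`.
#' @return list of class `transition_locked`: `matrix` (events x bins),
#'   `rel_t_labels_s`, `deep_nrem_db`, `awake_db`, `events`.
#' @export
timelock_transitions <- function(env_db, fs, events, epoch_len_s = 5,
                                 mask = NULL) {
  events <- events[events$valid, , drop = FALSE]
  n <- length(env_db)
  ml <- if (!is.null(mask)) mask_logical(mask, n, fs)
  keep <- rep(TRUE, nrow(events))
  for (k in seq_len(nrow(events))) {
    i0 <- events$nrem_onset_s[k] * fs + 1
    i1 <- (events$wake_onset_s[k] + events$wake_dur_s[k]) * fs
    if (i0 < 1 || i1 > n) {
      warning("event outside signal span dropped")
      keep[k] <- FALSE
    } else if (!is.null(ml) && mean(ml[i0:i1]) > 0.2) keep[k] <- FALSE
  }
  events <- events[keep, , drop = FALSE]
  if (!nrow(events)) stop("no usable transition events")

  k_lo <- -max(floor(events$nrem_dur_s / epoch_len_s))
  k_hi <- max(floor(events$wake_dur_s / epoch_len_s)) - 1L
  ks <- k_lo:k_hi
  rel_labels <- ks * epoch_len_s + epoch_len_s / 2
  M <- matrix(NA_real_, nrow = nrow(events), ncol = length(ks))
  deep <- awake <- rep(NA_real_, nrow(events))
  ep_mean <- function(t0, t1) {
    i0 <- round(t0 * fs) + 1L; i1 <- round(t1 * fs)
    if (i0 < 1 || i1 > n || i1 < i0) return(NA_real_)
    mean(env_db[i0:i1])
  }
  for (e in seq_len(nrow(events))) {
    w <- events$wake_onset_s[e]
    lo_k <- -floor(events$nrem_dur_s[e] / epoch_len_s)
    hi_k <- floor(events$wake_dur_s[e] / epoch_len_s) - 1L
    for (k in ks) {
      if (k < lo_k || k > hi_k) next
      M[e, k - k_lo + 1L] <- ep_mean(w + k * epoch_len_s,
                                     w + (k + 1L) * epoch_len_s)
    }
    # whole epochs inside [nrem_onset + 40, wake - 40] (deep NREM) and
    # [wake + 25, wake end] (awake)
    d0 <- events$nrem_onset_s[e] + 40; d1 <- w - 40
    dk <- ks[ks >= ceiling((d0 - w) / epoch_len_s - 1e-9) &
               ks <= floor((d1 - w) / epoch_len_s + 1e-9) - 1L]
    if (length(dk)) deep[e] <- mean(M[e, dk - k_lo + 1L], na.rm = TRUE)
    a0 <- w + 25; a1 <- w + events$wake_dur_s[e]
    ak <- ks[ks >= ceiling((a0 - w) / epoch_len_s - 1e-9) &
               ks <= floor((a1 - w) / epoch_len_s + 1e-9) - 1L]
    if (length(ak)) awake[e] <- mean(M[e, ak - k_lo + 1L], na.rm = TRUE)
  }
  structure(list(matrix = M, rel_t_labels_s = rel_labels,
                 deep_nrem_db = deep, awake_db = awake, events = events),
            class = "transition_locked")
}

#' Pre/post-awakening contrasts from transition-locked power
#'
#' Per event, the immediate pre-awakening bin (-7.5 s) and early post-wake
#' bin (+12.5 s) relative to the deep-NREM summary.
#'
#' @param tl a [timelock_transitions()] result.
#' @param pre_label,post_label relative bin labels in seconds.
#' @return data.frame: `pre_minus_deep`, `post_minus_deep` per event.
#' @export
transition_contrasts <- function(tl, pre_label = -7.5, post_label = 12.5) {
  stopifnot(inherits(tl, "transition_locked"))
  pick <- function(lab) {
    j <- which(abs(tl$rel_t_labels_s - lab) < 1e-9)
    if (!length(j)) rep(NA_real_, nrow(tl$matrix)) else tl$matrix[, j]
  }
  data.frame(pre_minus_deep = pick(pre_label) - tl$deep_nrem_db,
             post_minus_deep = pick(post_label) - tl$deep_nrem_db)
}
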