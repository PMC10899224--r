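## Epoch-wise Welch spectra, normalization schemes, band powers and
## cortico-subcortical magnitude-squared coherence.

#' Band definition schemes
#'
#' `analysis` is the scheme used for spectral/coupling analyses (delta 1-4,
#' theta 4-8, alpha 8-13, sigma 13-15, beta 13-31, gamma 31-50 Hz; sigma
#' deliberately overlaps beta). `ml` is the six-feature scheme used by the
#' classifier (delta 0-4, theta 4-8, alpha 8-13, sigma 13-15, high_beta
#' 15-31, low_gamma 31-50 Hz). Band edges are half-open `[lo, hi)`.
#'
#' @param name `"analysis"` or `"ml"`.
#' @return named list of `c(f_lo, f_hi)` pairs.
#' @export
band_scheme <- function(name = c("analysis", "ml")) {
  name <- match.arg(name)
  if (name == "analysis")
    list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
         sigma = c(13, 15), beta = c(13, 31), gamma = c(31, 50))
  else
    list(delta = c(0, 4), theta = c(4, 8), alpha = c(8, 13),
         sigma = c(13, 15), high_beta = c(15, 31), low_gamma = c(31, 50))
}

.normalize_psd <- function(psd, freqs, norm_mode) {
  tot <- switch(norm_mode,
    total_0_50 = sum(psd[freqs <= 50]),
    exclude_beta = sum(psd[freqs < 13 | (freqs >= 31 & freqs <= 50)]),
    none = 1)
  if (norm_mode != "none" && tot > 0) psd / tot else psd
}

#' Epoch-wise Welch power spectra for one channel
#'
#' Splits the (night-z-scored) signal into non-overlapping epochs on the
#' [epoch_grid()], computes the Welch PSD of each (1 s Hamming segments, 50%
#' overlap, 512-point transform) and applies the requested normalization on
#' linear power. Epochs with more than `max_masked_frac` masked samples are
#' skipped.
#'
#' @param x signal vector (z-scored per night).
#' @param fs sampling rate, Hz.
#' @param epoch_len_s epoch length, seconds (5 or 30).
#' @param norm_mode `"total_0_50"` (bin-sum over 0-50 Hz equals 1),
#'   `"exclude_beta"` (normalizer omits 13-31 Hz) or `"none"`.
#' @param mask optional `artifact_mask`; contaminated epochs are skipped.
#' @param max_masked_frac maximum tolerated masked fraction per epoch.
#' @return list with `freqs`, `psd` (epochs x bins, linear), and `epochs`
#'   (data.frame `epoch_index`, `t_label_s`).
#' @export
epoch_psd <- function(x, fs, epoch_len_s = 5,
                      norm_mode = c("total_0_50", "exclude_beta", "none"),
                      mask = NULL, max_masked_frac = 0.2) {
  norm_mode <- match.arg(norm_mode)
  stopifnot(epoch_len_s * fs >= fs)          # at least one 1 s segment
  grid <- epoch_grid(length(x) / fs, epoch_len_s)
  ml <- if (!is.null(mask)) mask_logical(mask, length(x), fs)
  keep <- rep(TRUE, nrow(grid))
  rows <- vector("list", nrow(grid))
  freqs <- NULL
  for (k in seq_len(nrow(grid))) {
    i0 <- round(grid$start_s[k] * fs) + 1L
    i1 <- round(grid$stop_s[k] * fs)
    if (!is.null(ml) && mean(ml[i0:i1]) > max_masked_frac) {
      keep[k] <- FALSE
      next
    }
    p <- welch_psd(x[i0:i1], fs)
    freqs <- p$freqs
    rows[[k]] <- .normalize_psd(p$psd, p$freqs, norm_mode)
  }
  psd <- do.call(rbind, rows[keep])
  list(freqs = freqs, psd = psd,
       epochs = data.frame(epoch_index = which(keep) - 1L,
                           t_label_s = grid$t_label_s[keep]),
       norm_mode = norm_mode)
}

#' Band powers (dB) from epoch spectra
#'
#' Per band, the linear PSD bins with `f_lo <= f < f_hi` are summed and
#' converted to decibels (`10 log10`). A zero in-band power is floored at
#' -300 dB.
#'
#' @param spec an [epoch_psd()] result.
#' @param scheme a [band_scheme()] list (or its name).
#' @return data.frame: `epoch_index`, `t_label_s`, one dB column per band.
#' @export
band_powers <- function(spec, scheme = "analysis") {
  if (is.character(scheme)) scheme <- band_scheme(scheme)
  f <- spec$freqs
  out <- spec$epochs
  for (bd in names(scheme)) {
    sel <- f >= scheme[[bd]][1] & f < scheme[[bd]][2]
    if (!any(sel)) stop("band ", bd, " outside the frequency range")
    v <- rowSums(spec$psd[, sel, drop = FALSE])
    out[[bd]] <- ifelse(v > 0, 10 * log10(v), -300)
  }
  out
}

#' Magnitude-squared coherence for one simultaneous epoch pair
#'
#' Welch-averaged MSC with 1 s Hamming segments, 50% overlap and a 512-point
#' transform.
#'
#' @param cort,subcort equal-length signal epochs.
#' @param fs sampling rate, Hz.
#' @return list with `freqs` and `msc` in `[0, 1]`.
#' @export
coherence_epoch <- function(cort, subcort, fs) {
  welch_msc(cort, subcort, fs)
}

#' Per-epoch stage labels for a hypnogram at a given epoch length
#'
#' @param h a [new_hypnogram()].
#' @param epoch_len_s 5 or 30; the 5 s track uses re-scored fine labels when
#'   present.
#' @param n_epochs truncate/pad-check to this many epochs.
#' @return character vector of stage labels.
#' @export
stage_labels <- function(h, epoch_len_s, n_epochs = NULL) {
  lab <- if (epoch_len_s == 30) h$stages
    else if (epoch_len_s == 5) expand_stages(h)
    else stop("stage labels available at 5 s or 30 s resolution only")
  if (!is.null(n_epochs)) {
    if (n_epochs > length(lab))
      lab <- c(lab, rep("U", n_epochs - length(lab)))
    lab <- lab[seq_len(n_epochs)]
  }
  lab
}

#' Epoch band-power table for a whole recording
#'
#' The workhorse feature extractor: per channel, z-scores the night, computes
#' epoch-wise Welch spectra, applies the normalization, sums bands and
#' attaches stage labels and channel/night metadata. Unscored (`U`) epochs
#' are dropped.
#'
#' @param rec conditioned [new_recording()].
#' @param h matching [new_hypnogram()].
#' @param epoch_len_s 5 or 30 s epochs.
#' @param scheme band scheme name or list (see [band_scheme()]).
#' @param norm_mode normalization (see [epoch_psd()]).
#' @param masks optional named list of `artifact_mask` per hemisphere.
#' @param zscore z-score each channel first (skip when `rec` already is).
#' @return data.frame with metadata columns plus one dB column per band and
#'   a `norm_mode` column.
#' @export
epoch_band_powers <- function(rec, h, epoch_len_s = 5, scheme = "analysis",
                              norm_mode = "total_0_50", masks = NULL,
                              zscore = TRUE) {
  stopifnot(inherits(rec, "fp_recording"), inherits(h, "hypnogram"))
  out <- list()
  for (ci in seq_len(nrow(rec$channels))) {
    x <- rec$samples[ci, ]
    if (zscore) x <- (x - mean(x)) / stats::sd(x)
    hem <- rec$channels$hemisphere[ci]
    mask <- if (!is.null(masks)) masks[[hem]]
    spec <- epoch_psd(x, rec$fs, epoch_len_s, norm_mode, mask = mask)
    bp <- band_powers(spec, scheme)
    lab <- stage_labels(h, epoch_len_s,
                        floor(ncol(rec$samples) / rec$fs / epoch_len_s))
    bp$stage <- lab[bp$epoch_index + 1L]
    bp$channel <- rec$channels$label[ci]
    bp$region <- rec$channels$region[ci]
    bp$hemisphere <- hem
    bp$night_id <- rec$night_id
    bp$participant_id <- rec$participant_id
    bp$stim_state <- rec$stim_state
    bp$norm_mode <- norm_mode
    out[[ci]] <- bp[bp$stage != "U", ]
  }
  do.call(rbind, out)
}

#' Epoch-wise cortico-subcortical coherence spectra for a recording
#'
#' Per hemisphere, pairs the cortical and subcortical channel and computes
#' the MSC for every epoch.
#'
#' @inheritParams epoch_band_powers
#' @return list with `freqs`, `msc` (epochs x bins), and `epochs` metadata
#'   (`t_label_s`, `stage`, `hemisphere`, `night_id`).
#' @export
epoch_coherence <- function(rec, h, epoch_len_s = 5, masks = NULL,
                            zscore = TRUE) {
  stopifnot(inherits(rec, "fp_recording"))
  ch <- rec$channels
  rows <- list(); meta <- list(); freqs <- NULL
  n_ep <- floor(ncol(rec$samples) / rec$fs / epoch_len_s)
  lab <- stage_labels(h, epoch_len_s, n_ep)
  grid <- epoch_grid(ncol(rec$samples) / rec$fs, epoch_len_s)
  for (hem in unique(ch$hemisphere)) {
    si <- which(ch$region == "subcortex" & ch$hemisphere == hem)
    ci <- which(ch$region == "cortex" & ch$hemisphere == hem)
    if (!length(si) || !length(ci)) next
    xs <- rec$samples[si, ]; xc <- rec$samples[ci, ]
    if (zscore) {
      xs <- (xs - mean(xs)) / stats::sd(xs)
      xc <- (xc - mean(xc)) / stats::sd(xc)
    }
    ml <- if (!is.null(masks) && !is.null(masks[[hem]]))
      mask_logical(masks[[hem]], length(xs), rec$fs)
    for (k in seq_len(n_ep)) {
      if (lab[k] == "U") next
      i0 <- round(grid$start_s[k] * rec$fs) + 1L
      i1 <- round(grid$stop_s[k] * rec$fs)
      if (!is.null(ml) && mean(ml[i0:i1]) > 0.2) next
      m <- welch_msc(xc[i0:i1], xs[i0:i1], rec$fs)
      freqs <- m$freqs
      rows[[length(rows) + 1L]] <- m$msc
      meta[[length(meta) + 1L]] <-
        data.frame(t_label_s = grid$t_label_s[k], stage = lab[k],
                   hemisphere = hem, night_id = rec$night_id)
    }
  }
  list(freqs = freqs, msc = do.call(rbind, rows),
       epochs = do.call(rbind, meta))
}

#' Per-night stage-contrast curves (e.g. N2/N3 NREM minus wake)
#'
#' For each night, averages the log-transformed spectra (or dB band powers)
#' over the epochs of each stage group, pooling hemispheres by concatenating
#' epochs, and returns the stage_a minus stage_b difference. Nights missing
#' one of the stages are excluded with a warning.
#'
#' @param values epochs x bins matrix of linear power (or MSC), or a numeric
#'   vector already in dB.
#' @param stage,night per-epoch stage labels and night identifiers.
#' @param stage_a,stage_b stage groups to contrast (defaults: N2/N3 vs W).
#' @param log_transform average `10 log10(values)` (set `FALSE` for MSC or
#'   already-log values).
#' @return matrix nights x bins (or named vector for vector input) of
#'   differences.
#' @export
stage_contrast <- function(values, stage, night, stage_a = c("N2", "N3"),
                           stage_b = "W", log_transform = TRUE) {
  vec_in <- is.null(dim(values))
  if (vec_in) values <- matrix(values, ncol = 1)
  if (log_transform) values <- 10 * log10(pmax(values, 1e-30))
  nights <- unique(night)
  out <- list()
  for (nt in nights) {
    a <- night == nt & stage %in% stage_a
    b <- night == nt & stage %in% stage_b
    if (!any(a) || !any(b)) {
      warning("night ", nt, " lacks a contrasted stage; excluded")
      next
    }
    out[[nt]] <- colMeans(values[a, , drop = FALSE]) -
      colMeans(values[b, , drop = FALSE])
  }
  res <- do.call(rbind, out)
  if (vec_in) stats::setNames(res[, 1], rownames(res)) else res
}
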