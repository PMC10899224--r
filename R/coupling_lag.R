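## Inverse subcortical-beta / cortical-delta coupling within N2/N3 NREM and
## its lead-lag structure from 5 s epoch band-power series.

#' Extract aligned N2/N3 band-power series for the coupling analysis
#'
#' Builds the per-epoch (5 s) subcortical-beta and cortical-delta dB series
#' of one night, restricted to N2/N3 epochs, pooled over hemispheres by
#' concatenation. Cortical delta is normalized excluding the beta range
#' (13-31 Hz) to avoid normalization-induced spurious negative correlations;
#' for the cortical-cortical control pair no normalization is applied.
#'
#' @param rec conditioned [new_recording()].
#' @param h matching [new_hypnogram()].
#' @param pair `"subcort_beta:cort_delta"` or the cortical-cortical control
#'   `"cort_beta:cort_delta"`.
#' @param masks optional hemisphere masks from preprocessing.
#' @return data.frame: `predictor`, `response` (dB), `hemisphere`,
#'   `t_label_s`.
#' @export
coupling_series <- function(rec, h,
                            pair = c("subcort_beta:cort_delta",
                                     "cort_beta:cort_delta"),
                            masks = NULL) {
  pair <- match.arg(pair)
  ch <- rec$channels
  cortical_control <- pair == "cort_beta:cort_delta"
  norm_resp <- if (cortical_control) "none" else "exclude_beta"
  norm_pred <- if (cortical_control) "none" else "total_0_50"
  out <- list()
  n_ep <- floor(ncol(rec$samples) / rec$fs / 5)
  lab <- stage_labels(h, 5, n_ep)
  for (hem in unique(ch$hemisphere)) {
    pi_ <- which(ch$hemisphere == hem &
                   ch$region == if (cortical_control) "cortex" else "subcortex")
    ri <- which(ch$hemisphere == hem & ch$region == "cortex")
    if (!length(pi_) || !length(ri)) next
    mask <- if (!is.null(masks)) masks[[hem]]
    z <- function(v) (v - mean(v)) / stats::sd(v)
    ps <- epoch_psd(z(rec$samples[pi_, ]), rec$fs, 5, norm_pred, mask = mask)
    rs <- epoch_psd(z(rec$samples[ri, ]), rec$fs, 5, norm_resp, mask = mask)
    pb <- band_powers(ps, band_scheme("analysis")["beta"])
    rb <- band_powers(rs, band_scheme("analysis")["delta"])
    keep <- lab[pb$epoch_index + 1L] %in% c("N2", "N3")
    if (!any(keep)) next
    out[[hem]] <- data.frame(predictor = pb$beta[keep],
                             response = rb$delta[keep],
                             hemisphere = rep(hem, sum(keep)),
                             t_label_s = pb$t_label_s[keep])
  }
  do.call(rbind, out)
}

#' Spearman coupling between two epoch band-power series
#'
#' Rank correlation (two-sided) between the predictor (subcortical beta) and
#' response (cortical delta) dB series across all N2/N3 5 s epochs of a
#' night, optionally after 20-point Gaussian smoothing of both series.
#'
#' @param beta_series,delta_series aligned per-epoch dB vectors.
#' @param smooth apply 20-point Gaussian smoothing first.
#' @param min_epochs validity threshold on the epoch count.
#' @return list(`rho`, `p_value`, `n_epochs`, `valid`) of class
#'   `coupling_result`.
#' @export
coupling_correlation <- function(beta_series, delta_series, smooth = FALSE,
                                 min_epochs = 10) {
  stopifnot(length(beta_series) == length(delta_series))
  n <- length(beta_series)
  if (smooth && n >= 3) {
    beta_series <- gaussian_smooth(beta_series, 20)
    delta_series <- gaussian_smooth(delta_series, 20)
  }
  if (n < min_epochs)
    return(structure(list(rho = NA_real_, p_value = NA_real_, n_epochs = n,
                          valid = FALSE), class = "coupling_result"))
  ct <- suppressWarnings(
    stats::cor.test(beta_series, delta_series, method = "spearman",
                    exact = FALSE))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value,
                 n_epochs = n, valid = TRUE),
            class = "coupling_result")
}

#' Lead-lag between subcortical beta and cortical delta power
#'
#' Both 5 s epoch series are smoothed with a 20-point Gaussian kernel and
#' mean-subtracted, then the normalized cross-correlation is evaluated over
#' `+/- max_lag_epochs` and the lag at its minimum (the trough, reflecting
#' the negative relationship) is returned. Sign convention, with the
#' response (cortical delta) as reference: `lag_s < 0` means the predictor
#' (subcortical beta) precedes the response.
#'
#' @param beta_series,delta_series aligned per-epoch dB vectors
#'   (predictor, response).
#' @param max_lag_epochs lag search range in 5 s epochs.
#' @param epoch_len_s epoch length, seconds.
#' @param smooth apply the 20-point Gaussian smoothing (disable only for
#'   oracle checks).
#' @return list(`lag_s`, `lag_epochs`, `ncc_curve`, `lags_s`,
#'   `trough_value`) of class `lag_result`.
#' @export
coupling_lag <- function(beta_series, delta_series, max_lag_epochs = 24,
                         epoch_len_s = 5, smooth = TRUE) {
  stopifnot(length(beta_series) == length(delta_series))
  if (stats::sd(beta_series) == 0 || stats::sd(delta_series) == 0)
    stop("flat band-power series: lag undefined")
  if (smooth) {
    beta_series <- gaussian_smooth(beta_series, 20)
    delta_series <- gaussian_smooth(delta_series, 20)
  }
  # r(l) = sum_t response(t) predictor(t + l): trough at negative l when the
  # predictor leads the response
  xc <- norm_xcorr(delta_series, beta_series, max_lag = max_lag_epochs,
                   demean = TRUE)
  i <- which.min(xc$ncc)
  structure(list(lag_s = xc$lags[i] * epoch_len_s,
                 lag_epochs = xc$lags[i],
                 ncc_curve = xc$ncc, lags_s = xc$lags * epoch_len_s,
                 trough_value = xc$ncc[i]),
            class = "lag_result")
}

#' Pool lag cross-correlation curves across nights
#'
#' Averages the normalized cross-correlation curves of several
#' [coupling_lag()] results (same lag grid) and returns the trough of the
#' pooled curve -- the stable multi-night lag estimate.
#'
#' @param lag_results list of `lag_result` objects.
#' @return a `lag_result` for the pooled curve.
#' @export
pool_lag_curves <- function(lag_results) {
  lag_results <- Filter(Negate(is.null), lag_results)
  stopifnot(length(lag_results) > 0)
  ncc <- Reduce(`+`, lapply(lag_results, `[[`, "ncc_curve")) /
    length(lag_results)
  lags_s <- lag_results[[1]]$lags_s
  i <- which.min(ncc)
  structure(list(lag_s = lags_s[i], lag_epochs = lags_s[i] / 5,
                 ncc_curve = ncc, lags_s = lags_s, trough_value = ncc[i]),
            class = "lag_result")
}

#' Full coupling analysis of one night
#'
#' Convenience wrapper: builds the N2/N3 series via [coupling_series()] and
#' returns the Spearman coupling and trough lag.
#'
#' @inheritParams coupling_series
#' @param max_lag_epochs lag search range in 5 s epochs.
#' @return list(`correlation`, `lag`, `n_epochs`).
#' @export
night_coupling <- function(rec, h, pair = "subcort_beta:cort_delta",
                           masks = NULL, max_lag_epochs = 24) {
  s <- coupling_series(rec, h, pair, masks)
  # correlation pools hemispheres by concatenation; the lag curve is
  # estimated per hemisphere and averaged, avoiding a seam artifact
  lag <- NULL
  hems <- split(s, s$hemisphere)
  ok <- vapply(hems, function(d) nrow(d) > 2 * max_lag_epochs + 10, TRUE)
  if (any(ok)) {
    curves <- lapply(hems[ok], function(d)
      coupling_lag(d$predictor, d$response, max_lag_epochs))
    ncc <- Reduce(`+`, lapply(curves, `[[`, "ncc_curve")) / sum(ok)
    i <- which.min(ncc)
    lag <- structure(list(lag_s = curves[[1]]$lags_s[i],
                          lag_epochs = curves[[1]]$lags_s[i] / 5,
                          ncc_curve = ncc, lags_s = curves[[1]]$lags_s,
                          trough_value = ncc[i]),
                     class = "lag_result")
  }
  list(correlation = coupling_correlation(s$predictor, s$response),
       lag = lag, n_epochs = nrow(s))
}
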