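## Shared signal-processing primitives: Welch (cross-)spectra on stats::fft,
## the analytic signal, Gaussian kernel smoothing, normalized cross-correlation.

.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Gaussian smoothing kernel with fixed support
#'
#' Kernel truncated at +/- 3 sigma with total support `support` samples, i.e.
#' `sigma = support / 6` (the standard window-to-sigma convention); normalized
#' to unit sum.
#'
#' @param support total kernel support in samples.
#' @return numeric kernel vector of odd length.
#' @export
gaussian_kernel <- function(support) {
  sigma <- support / 6
  half <- max(1L, floor(support / 2))
  t <- (-half):half
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

#' Smooth a series with a Gaussian kernel (edge-renormalized)
#'
#' @param x numeric vector.
#' @param support kernel support in samples (see [gaussian_kernel()]).
#' @return smoothed vector, same length as `x`.
#' @export
gaussian_smooth <- function(x, support) {
  k <- gaussian_kernel(support)
  half <- (length(k) - 1L) %/% 2L
  n <- length(x)
  num <- stats::convolve(c(rep(0, half), x, rep(0, half)), rev(k),
                         type = "filter")
  den <- stats::convolve(c(rep(0, half), rep(1, n), rep(0, half)), rev(k),
                         type = "filter")
  num / den
}

## Segment start indices for Welch averaging within one epoch.
.welch_segments <- function(n, seg_len, overlap = 0.5) {
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  starts
}

## One-sided Welch auto/cross spectral matrix for a list of signals.
## Returns freqs and a function of (i, j) -> averaged cross-spectrum S_ij(f).
.welch_xspec <- function(sigs, fs, seg_len, nfft, overlap = 0.5) {
  n <- length(sigs[[1]])
  if (n < seg_len) stop("epoch shorter than one Welch segment")
  w <- .hamming(seg_len)
  starts <- .welch_segments(n, seg_len, overlap)
  nf <- nfft %/% 2L + 1L
  ffts <- lapply(sigs, function(x) {
    out <- matrix(0 + 0i, nrow = nf, ncol = length(starts))
    for (s in seq_along(starts)) {
      seg <- x[starts[s]:(starts[s] + seg_len - 1L)] * w
      X <- stats::fft(c(seg, rep(0, nfft - seg_len)))
      out[, s] <- X[seq_len(nf)]
    }
    out
  })
  list(freqs = (seq_len(nf) - 1L) * fs / nfft,
       cross = function(i, j) rowMeans(ffts[[i]] * Conj(ffts[[j]])),
       n_segments = length(starts))
}

#' Welch power spectral density of one epoch
#'
#' 1 s Hamming segments with 50% overlap, zero-padded to a 512-point
#' transform (the pipeline's fixed spectral estimator). One-sided density in
#' power units (window-energy normalized).
#'
#' @param x numeric signal vector (one epoch).
#' @param fs sampling rate in Hz.
#' @param seg_len_s Welch segment length in seconds.
#' @param nfft transform length (zero-padded).
#' @param overlap fractional segment overlap.
#' @return list with `freqs` (Hz), `psd` (one-sided density, power/Hz: the
#'   bin sum times `fs/nfft` recovers the signal variance) and `n_segments`.
#' @export
welch_psd <- function(x, fs, seg_len_s = 1, nfft = 512L, overlap = 0.5) {
  seg_len <- round(seg_len_s * fs)
  xs <- .welch_xspec(list(x), fs, seg_len, nfft, overlap)
  w <- .hamming(seg_len)
  pxx <- Re(xs$cross(1, 1)) / (fs * sum(w^2))
  nf <- length(pxx)
  # one-sided: double the interior bins
  pxx[2:(nf - 1L)] <- 2 * pxx[2:(nf - 1L)]
  list(freqs = xs$freqs, psd = pxx, n_segments = xs$n_segments)
}

#' Welch magnitude-squared coherence of one epoch pair
#'
#' Same segmentation as [welch_psd()]: 1 s Hamming segments, 50% overlap,
#' 512-point transform; `msc = |Sxy|^2 / (Sxx Syy)` from segment-averaged
#' spectra.
#'
#' @param x,y equal-length signal vectors.
#' @inheritParams welch_psd
#' @return list with `freqs`, `msc` and `n_segments`.
#' @export
welch_msc <- function(x, y, fs, seg_len_s = 1, nfft = 512L, overlap = 0.5) {
  if (length(x) != length(y)) stop("coherence inputs must have equal length")
  seg_len <- round(seg_len_s * fs)
  xs <- .welch_xspec(list(x, y), fs, seg_len, nfft, overlap)
  sxx <- Re(xs$cross(1, 1)); syy <- Re(xs$cross(2, 2))
  sxy <- xs$cross(1, 2)
  msc <- Mod(sxy)^2 / (sxx * syy)
  msc[!is.finite(msc)] <- 0
  list(freqs = xs$freqs, msc = pmin(msc, 1), n_segments = xs$n_segments)
}

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' @param x real signal vector.
#' @return complex vector whose modulus is the instantaneous amplitude.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Normalized cross-correlation over a lag range
#'
#' `r(l) = sum_t a(t) b(t + l) / sqrt(sum a^2 sum b^2)` computed after
#' optional mean removal; lags in samples, positive lag meaning `b` is read
#' ahead of `a`.
#'
#' @param a,b numeric vectors (equal length).
#' @param max_lag maximum absolute lag in samples.
#' @param demean subtract each series' mean first.
#' @return list with `lags` (samples) and `ncc`.
#' @export
norm_xcorr <- function(a, b, max_lag, demean = TRUE) {
  if (length(a) != length(b)) stop("series must have equal length")
  if (demean) { a <- a - mean(a); b <- b - mean(b) }
  denom <- sqrt(sum(a^2) * sum(b^2))
  if (denom == 0) stop("zero-variance series: cross-correlation undefined")
  n <- length(a)
  lags <- (-max_lag):max_lag
  r <- vapply(lags, function(l) {
    if (l >= 0) sum(a[1:(n - l)] * b[(1 + l):n])
    else sum(a[(1 - l):n] * b[1:(n + l)])
  }, 0)
  list(lags = lags, ncc = r / denom)
}

## Linear-interpolation resampler onto a uniform grid at target_fs.
.resample_lin <- function(x, fs, target_fs) {
  n <- length(x)
  t_old <- (seq_len(n) - 1) / fs
  t_new <- seq(0, t_old[n], by = 1 / target_fs)
  stats::approx(t_old, x, xout = t_new)$y
}
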