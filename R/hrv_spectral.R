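#' @title Frequency-domain analysis
#' @description Burg autoregressive and Welch spectra of the uniformly
#'   resampled, detrended tachogram, with band powers over the conventional
#'   short-term bands VLF `[0.0033, 0.04)`, LF `[0.04, 0.15)` and HF
#'   `[0.15, 0.4)` Hz. The LF/HF ratio uses absolute band powers; an LF/HF
#'   above 1 is conventionally read as sympathetic dominance.
#' @name ambuhrv-spectral
NULL

hrv_bands <- list(vlf = c(0.0033, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.40))

trapz_band <- function(freqs, psd, band) {
  sel <- freqs >= band[1] & freqs < band[2]
  f <- freqs[sel]; p <- psd[sel]
  if (length(f) < 2L) return(0)
  sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

spectrum_result <- function(freqs, psd, method, ar_order = NA_integer_) {
  vlf <- trapz_band(freqs, psd, hrv_bands$vlf)
  lf <- trapz_band(freqs, psd, hrv_bands$lf)
  hf <- trapz_band(freqs, psd, hrv_bands$hf)
  tot <- lf + hf
  structure(list(
    freqs = freqs, psd = psd, method = method, ar_order = ar_order,
    vlf_power = vlf, lf_power = lf, hf_power = hf,
    lf_hf = if (hf > 0) lf / hf else NA_real_,
    lf_nu = if (tot > 0) 100 * lf / tot else NA_real_,
    hf_nu = if (tot > 0) 100 * hf / tot else NA_real_
  ), class = "hrv_spectrum")
}

#' @export
print.hrv_spectrum <- function(x, ...) {
  cat(sprintf("<hrv_spectrum> %s: LF %.2f ms2, HF %.2f ms2, LF/HF %.3f\n",
              x$method, x$lf_power, x$hf_power, x$lf_hf))
  invisible(x)
}

#' Autoregressive (Burg) power spectral density
#'
#' Fits an AR model by Burg recursion (via [stats::ar()]) to the zero-meaned
#' tachogram and evaluates the parametric PSD on a dense grid over
#' `[0, fs/2]`. Band powers are obtained by trapezoidal integration.
#'
#' @param tach an `rr_tachogram` (detrended, uniform).
#' @param order AR model order (default 16, a common short-term HRV choice).
#' @param n_freq number of PSD grid points (at least 1025 used).
#' @return an `hrv_spectrum`.
#' @export
ar_psd <- function(tach, order = 16L, n_freq = 1025L) {
  stopifnot(inherits(tach, "rr_tachogram"))
  x <- tach$rr - mean(tach$rr)
  n <- length(x)
  if (order >= n / 2) stop_model_order_error(
    sprintf("AR order %d too large for %d samples", order, n))
  if (n < 10L * order) stop_inadequate_length(
    sprintf("need at least %d samples for order %d", 10L * order, order))
  fs <- tach$fs
  freqs <- seq(0, fs / 2, length.out = max(n_freq, 1025L))
  if (stats::var(x) == 0) return(spectrum_result(freqs, numeric(length(freqs)),
                                                 "ar_burg", as.integer(order)))
  fit <- stats::ar(x, aic = FALSE, order.max = order, method = "burg",
                   demean = FALSE)
  a <- fit$ar
  # two-sided AR PSD sigma^2 / (fs |1 - sum a_k z^-k|^2), doubled one-sided
  ek <- exp(-2i * pi * outer(freqs / fs, seq_along(a)))
  denom <- Mod(1 - as.vector(ek %*% a))^2
  psd <- 2 * fit$var.pred / (fs * denom)
  spectrum_result(freqs, psd, "ar_burg", as.integer(order))
}

#' Welch segment-averaged periodogram
#'
#' Hann-windowed, 50%-overlapping segment-averaged periodogram of the
#' zero-meaned tachogram, normalized so that the one-sided PSD integrates
#' to the signal variance (Parseval). Serves as the nonparametric
#' cross-check of [ar_psd()].
#'
#' @param tach an `rr_tachogram`.
#' @param seg_len segment length in samples (power of two; shortened
#'   automatically for short inputs).
#' @return an `hrv_spectrum`.
#' @export
welch_psd <- function(tach, seg_len = 256L) {
  stopifnot(inherits(tach, "rr_tachogram"))
  x <- tach$rr - mean(tach$rr)
  n <- length(x)
  if (n < 64L) stop_inadequate_length("need at least 64 samples")
  seg_len <- min(seg_len, 2L^floor(log2(n)))
  fs <- tach$fs
  step <- seg_len %/% 2L
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  u <- sum(w^2)
  nf <- seg_len %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    X <- stats::fft(seg)[seq_len(nf)]
    p <- Mod(X)^2 / (fs * u)
    p[c(-1, -nf)] <- 2 * p[c(-1, -nf)]
    acc <- acc + p
  }
  psd <- acc / length(starts)
  freqs <- seq(0, fs / 2, length.out = nf)
  spectrum_result(freqs, psd, "welch")
}
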