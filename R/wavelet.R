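#' @title Orthogonal wavelet machinery
#' @description A compact periodic Daubechies discrete wavelet transform
#'   used by [detrend_wavelet()]. Only the approximation branch of the
#'   packet tree is needed for lowpass trend removal: iterating the
#'   analysis lowpass `depth` times isolates the band `[0, fs/2^(depth+1)]`,
#'   which is zeroed and the signal reconstructed.
#' @name ambuhrv-wavelet
#' @keywords internal
NULL

# Daubechies D4 (2 vanishing moments): annihilates linear trends in the
# detail bands, so a ramp is carried almost entirely by the approximation.
daub4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- rev(h) * c(1, -1, 1, -1)  # g_k = (-1)^k h_{L-1-k}
  list(h = h, g = g)
}

# One analysis level (periodic boundary). x length must be even.
dwt_step <- function(x, filt) {
  n <- length(x)
  half <- n %/% 2L
  L <- length(filt$h)
  a <- numeric(half); d <- numeric(half)
  k <- seq_len(half) - 1L
  for (m in seq_len(L) - 1L) {
    idx <- (2L * k + m) %% n + 1L
    a <- a + filt$h[m + 1L] * x[idx]
    d <- d + filt$g[m + 1L] * x[idx]
  }
  list(a = a, d = d)
}

# One synthesis level (periodic boundary), inverse of dwt_step.
idwt_step <- function(a, d, filt) {
  half <- length(a)
  n <- 2L * half
  L <- length(filt$h)
  x <- numeric(n)
  k <- seq_len(half) - 1L
  for (m in seq_len(L) - 1L) {
    idx <- (2L * k + m) %% n + 1L
    contrib <- filt$h[m + 1L] * a + filt$g[m + 1L] * d
    x[idx] <- x[idx] + contrib
  }
  x
}

# Decompose along the approximation path, zero the deepest approximation,
# reconstruct. Length of x must be a multiple of 2^depth.
wavelet_highpass <- function(x, depth, filt = daub4_filters()) {
  details <- vector("list", depth)
  a <- x
  for (lev in seq_len(depth)) {
    st <- dwt_step(a, filt)
    details[[lev]] <- st$d
    a <- st$a
  }
  a <- numeric(length(a))  # remove the lowest band
  for (lev in rev(seq_len(depth))) {
    a <- idwt_step(a, details[[lev]], filt)
  }
  a
}

#' Wavelet detrending of a uniform tachogram
#'
#' Removes the very-low-frequency trend by zeroing the lowest band of an
#' orthogonal Daubechies decomposition. The decomposition depth is the
#' smallest for which the lowest band `[0, fs/2^(depth+1)]` lies within
#' `[0, cutoff]`; with the 4 Hz default grid and the 0.0391 Hz cutoff this
#' is depth 6 (band `[0, 0.03125]` Hz). The signal is reflection-padded at
#' both ends to a multiple of the block size before the periodic transform,
#' which suppresses boundary leakage from non-stationary trends.
#'
#' @param tach an `rr_tachogram` from [resample_tachogram()].
#' @param cfg a [preprocess_config()]; `detrend_cutoff_hz` sets the band.
#' @return an `rr_tachogram` with the trend removed (`rr` is close to
#'   zero-mean); the removed trend is attached as attribute `"trend"`.
#' @export
detrend_wavelet <- function(tach, cfg = preprocess_config()) {
  stopifnot(inherits(tach, "rr_tachogram"))
  fs <- tach$fs
  depth <- ceiling(log2((fs / 2) / cfg$detrend_cutoff_hz))
  block <- 2L^depth
  x <- tach$rr
  n <- length(x)
  if (n < block)
    stop_inadequate_length(sprintf("need at least %d samples for depth-%d detrend",
                                   block, depth))
  margin <- block
  total <- ceiling((n + 2L * margin) / block) * block
  lp <- margin
  rp <- total - n - lp
  left <- rev(x[seq(2L, lp + 1L)])
  right <- rev(x[seq(n - rp, n - 1L)])
  padded <- c(left, x, right)
  hp <- wavelet_highpass(padded, depth)
  out <- hp[(lp + 1L):(lp + n)]
  res <- structure(list(t = tach$t, rr = out, fs = fs), class = "rr_tachogram")
  attr(res, "trend") <- x - out
  res
}
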