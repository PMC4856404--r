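#' Basic time-domain statistics
#'
#' Mean heart rate, SDNN and RMSSD over the normal (NN) intervals.
#' `mean_hr = 60000 / mean(NN)` (bpm); SDNN is the population standard
#' deviation by default (switchable via `sd_mode` in the config); RMSSD is
#' the root mean square of successive differences.
#'
#' @param series an [rr_series()] (corrected); only `normal`-labelled
#'   intervals enter.
#' @param cfg a [preprocess_config()] (for `sd_mode`).
#' @return list with `mean_hr` (bpm), `sdnn` (ms), `rmssd` (ms).
#' @export
basic_time_stats <- function(series, cfg = preprocess_config()) {
  nn <- if (inherits(series, "rr_series")) nn_intervals(series) else as.numeric(series)
  if (length(nn) < 2L) stop_inadequate_length("need at least 2 NN intervals")
  n <- length(nn)
  sdnn <- if (identical(cfg$sd_mode, "sample")) {
    stats::sd(nn)
  } else {
    sqrt(sum((nn - mean(nn))^2) / n)
  }
  list(
    mean_hr = 60000 / mean(nn),
    sdnn = sdnn,
    rmssd = sqrt(mean(diff(nn)^2))
  )
}

nn_histogram <- function(nn, bin_width) {
  # bins aligned to multiples of bin_width: bin j covers [j*bw, (j+1)*bw)
  j <- floor(nn / bin_width)
  jr <- seq(min(j), max(j))
  counts <- tabulate(j - min(j) + 1L, nbins = length(jr))
  list(centers = (jr + 0.5) * bin_width, counts = counts,
       edges = c(jr, max(jr) + 1L) * bin_width)
}

#' HRV triangular index
#'
#' Total NN count divided by the height (count) of the modal bin of the NN
#' histogram, with bins of width `bin_width` aligned to multiples of
#' `bin_width`. The conventional width is 1/128 s = 7.8125 ms.
#'
#' @param series an [rr_series()] or numeric NN vector (ms).
#' @param bin_width histogram bin width (ms).
#' @return the triangular index (dimensionless, `>= 1`).
#' @export
triangular_index <- function(series, bin_width = 7.8125) {
  nn <- if (inherits(series, "rr_series")) nn_intervals(series) else as.numeric(series)
  if (length(nn) < 20L) stop_inadequate_length("need at least 20 NN intervals")
  h <- nn_histogram(nn, bin_width)
  length(nn) / max(h$counts)
}

#' Triangular interpolation of the NN histogram (TINN)
#'
#' Width `M - N` of the triangle that best fits the NN histogram in the
#' least-squares sense: the triangle is zero outside `[N, M]`, rises
#' linearly to the modal bin height at the mode, and falls linearly to zero
#' at `M`. `N` and `M` are found by exhaustive search over bin positions
#' with `N < mode < M`. A degenerate single-bin histogram yields
#' `tinn = bin_width`, the minimum representable base.
#'
#' @inheritParams triangular_index
#' @return TINN in ms.
#' @export
tinn <- function(series, bin_width = 7.8125) {
  nn <- if (inherits(series, "rr_series")) nn_intervals(series) else as.numeric(series)
  if (length(nn) < 20L) stop_inadequate_length("need at least 20 NN intervals")
  h <- nn_histogram(nn, bin_width)
  ctr <- h$centers
  cnt <- h$counts
  nb <- length(cnt)
  if (sum(cnt > 0) <= 1L) return(bin_width)
  mode_i <- which.max(cnt)
  y <- cnt[mode_i]
  tm <- ctr[mode_i]
  # candidate bases one bin beyond each side so a triangle can reach zero
  n_cand <- c(ctr[1] - bin_width, ctr[seq_len(max(mode_i - 1L, 0L))])
  m_cand <- c(ctr[mode_i + seq_len(nb - mode_i)], ctr[nb] + bin_width)
  best <- Inf; best_n <- tm - bin_width / 2; best_m <- tm + bin_width / 2
  for (N in n_cand) {
    for (M in m_cand) {
      tri <- numeric(nb)
      left <- ctr > N & ctr <= tm
      right <- ctr > tm & ctr < M
      tri[left] <- y * (ctr[left] - N) / (tm - N)
      tri[right] <- y * (M - ctr[right]) / (M - tm)
      tri[mode_i] <- y
      err <- sum((cnt - tri)^2)
      if (err < best) {
        best <- err; best_n <- N; best_m <- M
      }
    }
  }
  best_m - best_n
}
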