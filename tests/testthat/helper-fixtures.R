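# Shared fixture builders. Everything is generated in code at test time.

# uniform tachogram wrapper around a plain numeric vector
make_tach <- function(rr, fs = 4) {
  structure(list(t = (seq_along(rr) - 1) / fs, rr = rr, fs = fs),
            class = "rr_tachogram")
}

# a clean, stationary modulated segment for pipeline-level tests
make_clean_segment <- function(seed = 1, mean_rr = 700, duration_s = 300) {
  generate_rr_ipfm(synthetic_spec(
    duration_s = duration_s, mean_rr = mean_rr,
    a_lf = 0.02, a_hf = 0.015, fractal_alpha = 1.0, fractal_weight = 0.05,
    seed = seed))
}

# independent brute-force SampEn oracle: direct O(n^2) template counting
sampen_bruteforce <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  countA <- 0; countB <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dB <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dB <= r) {
        countB <- countB + 1
        dA <- max(abs(x[i:(i + m)] - x[j:(j + m)]))
        if (dA <= r) countA <- countA + 1
      }
    }
  }
  -log(countA / countB)
}

# independent exhaustive TINN oracle over bin-center candidates
tinn_bruteforce <- function(nn, bw = 7.8125) {
  j <- floor(nn / bw)
  jr <- seq(min(j), max(j))
  cnt <- tabulate(j - min(j) + 1L, nbins = length(jr))
  ctr <- (jr + 0.5) * bw
  mode_i <- which.max(cnt)
  y <- cnt[mode_i]; tm <- ctr[mode_i]
  n_cand <- c(ctr[1] - bw, ctr[seq_len(max(mode_i - 1L, 0L))])
  m_cand <- c(ctr[mode_i + seq_len(length(cnt) - mode_i)], ctr[length(cnt)] + bw)
  best <- Inf; bn <- NA; bm <- NA
  for (N in n_cand) for (M in m_cand) {
    tri <- ifelse(ctr <= N | ctr >= M, 0,
                  ifelse(ctr <= tm, y * (ctr - N) / (tm - N),
                         y * (M - ctr) / (M - tm)))
    err <- sum((cnt - tri)^2)
    if (err < best) { best <- err; bn <- N; bm <- M }
  }
  bm - bn
}
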