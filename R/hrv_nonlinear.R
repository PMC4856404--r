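#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A/B)` where `B` counts pairs of distinct templates of
#' length `m` that match within tolerance `r` (Chebyshev distance,
#' self-matches excluded) and `A` counts matching templates of length
#' `m + 1`. Lower values indicate more regular series. Computed on the
#' beat-domain NN series.
#'
#' @param x numeric series (NN intervals, ms) or an [rr_series()].
#' @param m template length (default 2).
#' @param r tolerance in the units of `x`; default `0.2 * sd(x)`.
#' @param min_beats minimum series length enforced (default 50, below which
#'   short-term SampEn estimates are unstable; relax only for validation
#'   exercises on constructed series).
#' @return sample entropy (dimensionless). If no `(m+1)`-templates match
#'   (`A == 0`) the value is `+Inf` with attribute `degenerate = TRUE`.
#' @export
sample_entropy <- function(x, m = 2L, r = NULL, min_beats = 50L) {
  if (inherits(x, "rr_series")) x <- nn_intervals(x)
  x <- as.numeric(x)
  n <- length(x)
  if (n < max(min_beats, m + 2L))
    stop_inadequate_length(sprintf("need at least %d beats for SampEn", min_beats))
  if (is.null(r)) r <- 0.2 * stats::sd(x)
  if (r < 0) stop_domain_error("tolerance r must be non-negative")

  count_matches <- function(mm) {
    nt <- n - m  # same template start set 1..(n-m) for both lengths
    if (nt < 2L || nt + mm - 1L > n) return(0)
    # Chebyshev distance between templates, built up one lag at a time
    dmax <- abs(outer(x[seq_len(nt)], x[seq_len(nt)], "-"))
    for (k in seq_len(mm - 1L)) {
      dk <- abs(outer(x[seq_len(nt) + k], x[seq_len(nt) + k], "-"))
      dmax <- pmax(dmax, dk)
    }
    (sum(dmax <= r) - nt) / 2  # distinct pairs, self-matches excluded
  }

  B <- count_matches(m)
  A <- count_matches(m + 1L)
  if (B == 0) stop_undefined_entropy()
  if (A == 0) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  -log(A / B)
}

#' Detrended fluctuation analysis
#'
#' Integrates the mean-centred series into a profile, splits it into
#' non-overlapping boxes of each requested size (taken from the start, tail
#' remainder dropped), removes a least-squares line per box, and returns
#' the RMS residual `F(n)` per box size.
#'
#' @param x numeric series or an [rr_series()] (NN intervals used).
#' @param box_sizes integer vector of box sizes; default `4:64` clipped to
#'   `n/4`.
#' @return a data.frame with columns `n` and `fn` (class `dfa_curve`).
#' @export
dfa <- function(x, box_sizes = NULL) {
  if (inherits(x, "rr_series")) x <- nn_intervals(x)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 100L) stop_inadequate_length("need at least 100 beats for DFA")
  if (stats::var(x) == 0) stop_degenerate_series()
  if (is.null(box_sizes)) box_sizes <- 4:min(64L, floor(n / 4))
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (any(box_sizes < 2L) || max(box_sizes) > n / 4)
    stop_domain_error("box sizes must be >= 2 and at most n/4")
  y <- cumsum(x - mean(x))
  fn <- vapply(box_sizes, function(b) {
    nbox <- n %/% b
    idx <- seq_len(nbox * b)
    seg <- matrix(y[idx], nrow = b)
    tt <- seq_len(b)
    # closed-form least-squares line per column
    st <- sum(tt); stt <- sum(tt^2)
    det <- b * stt - st^2
    sy <- colSums(seg)
    sty <- as.vector(tt %*% seg)
    slope <- (b * sty - st * sy) / det
    inter <- (stt * sy - st * sty) / det
    res <- seg - outer(tt, slope) - matrix(inter, nrow = b, ncol = nbox,
                                           byrow = TRUE)
    sqrt(mean(res^2))
  }, numeric(1))
  structure(data.frame(n = box_sizes, fn = fn),
            class = c("dfa_curve", "data.frame"))
}

#' Scaling exponents from a DFA fluctuation curve
#'
#' Least-squares slopes of `log10 F(n)` against `log10 n`: `alpha` over
#' boxes 4--64, the short-term `alpha1` over 4--16 and the long-term
#' `alpha2` over 16--64 (the conventional short-term HRV ranges).
#'
#' @param curve a `dfa_curve` from [dfa()].
#' @param range_all,range1,range2 inclusive box-size ranges for each fit.
#' @return list with `alpha`, `alpha1`, `alpha2`.
#' @export
dfa_alphas <- function(curve, range_all = c(4, 64), range1 = c(4, 16),
                       range2 = c(16, 64)) {
  stopifnot(is.data.frame(curve), all(c("n", "fn") %in% names(curve)))
  fit_range <- function(rg) {
    sel <- curve$n >= rg[1] & curve$n <= rg[2] & curve$fn > 0
    if (sum(sel) < 3L) stop_insufficient_scales(
      sprintf("fewer than 3 box sizes in [%d, %d]", rg[1], rg[2]))
    unname(stats::coef(stats::lm(log10(fn) ~ log10(n), data = curve[sel, ]))[2])
  }
  list(alpha = fit_range(range_all),
       alpha1 = fit_range(range1),
       alpha2 = fit_range(range2))
}
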