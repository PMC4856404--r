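#' Split a 300-s segment into two 150-s halves
#'
#' Time-based split at 150 s with half-open windows `[0, 150)` and
#' `[150, 300)`, so every beat belongs to exactly one half (the nominal
#' "0--150 / 151--300 s" labelling of split-half protocols, realized
#' contiguously so no beat is discarded).
#'
#' @param series a usable 300-s [rr_series()] segment.
#' @param min_beats minimum beats required in each half.
#' @return list with elements `f1` and `f2` ([rr_series()]).
#' @export
split_halves <- function(series, min_beats = 50L) {
  stopifnot(inherits(series, "rr_series"))
  if (duration_s(series, effective = TRUE) < 300 - 1e-9)
    stop_inadequate_length("split-half analysis requires a 300 s segment")
  f1 <- select_segment(series, 0, 150)
  f2 <- select_segment(series, 150, 150)
  if (n_beats(f1) < min_beats || n_beats(f2) < min_beats)
    stop_inadequate_length(sprintf("each half must contain at least %d beats",
                                   min_beats))
  list(f1 = f1, f2 = f2)
}

#' Spearman-Brown half-test correction
#'
#' Projects full-test reliability from the correlation `r` between two test
#' halves: `rhh = 2 r / (1 + r)`.
#'
#' @param r half-test Pearson correlation, in `(-1, 1]`.
#' @return the half-test reliability coefficient.
#' @export
spearman_brown <- function(r) {
  if (any(!is.finite(r)) || any(r <= -1) || any(r > 1))
    stop_domain_error("r must lie in (-1, 1]")
  2 * r / (1 + r)
}

#' Cronbach's alpha for two items
#'
#' Two-item form `alpha = 2 (1 - (var(F1) + var(F2)) / var(F1 + F2))`.
#'
#' @param f1,f2 numeric vectors of per-subject values for each half.
#' @return alpha in `(-Inf, 1]`.
#' @export
cronbach_alpha_2item <- function(f1, f2) {
  stopifnot(length(f1) == length(f2))
  if (length(f1) < 3L) stop_inadequate_sample("need at least 3 subjects")
  vt <- stats::var(f1 + f2)
  if (!is.finite(vt) || vt == 0)
    stop_domain_error("zero variance of the item sum; alpha undefined")
  2 * (1 - (stats::var(f1) + stats::var(f2)) / vt)
}

#' Average-measures intraclass correlation (two-way random effects)
#'
#' ICC from the two-way ANOVA decomposition of an n-subject x 2-half table.
#' The primary form is absolute agreement, average measures
#' (`(MSR - MSE) / (MSR + (MSC - MSE)/n)`); the consistency form
#' (`(MSR - MSE) / MSR`), which equals Cronbach's alpha for two items, is
#' reported alongside. The 95% confidence interval uses the F-based
#' interval for the single-measure agreement ICC with Satterthwaite
#' degrees of freedom, stepped up to average measures by the
#' Spearman-Brown relation.
#'
#' @param f1,f2 numeric vectors of per-subject values for each half.
#' @param conf confidence level (default 0.95).
#' @return list with `icc` (absolute agreement, average measures),
#'   `icc_consistency`, `ci` (length-2), and the ANOVA mean squares.
#' @export
icc_average <- function(f1, f2, conf = 0.95) {
  stopifnot(length(f1) == length(f2))
  n <- length(f1)
  if (n < 5L) stop_inadequate_sample("need at least 5 subjects for ICC")
  if (stats::var(c(f1, f2)) == 0)
    stop_domain_error("all values equal; ICC undefined")
  k <- 2L
  m <- cbind(f1, f2)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  icc_ak <- (msr - mse) / (msr + (msc - mse) / n)
  icc_ck <- (msr - mse) / msr
  icc_a1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # F-based CI for ICC(A,1), Satterthwaite df (McGraw & Wong), then
  # Spearman-Brown step-up to average measures.
  alpha <- 1 - conf
  fj <- if (mse > 0) msc / mse else Inf
  a1 <- icc_a1
  vn <- (k - 1) * (n - 1) *
    (k * a1 * fj + n * (1 + (k - 1) * a1) - k * a1)^2
  vd <- (n - 1) * k^2 * a1^2 * fj^2 +
    (n * (1 + (k - 1) * a1) - k * a1)^2
  v <- vn / vd
  ci <- suppressWarnings({
    f_u <- stats::qf(1 - alpha / 2, n - 1, v)
    f_l <- stats::qf(1 - alpha / 2, v, n - 1)
    l1 <- n * (msr - f_u * mse) /
      (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
    u1 <- n * (f_l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_l * msr)
    step_up <- function(r) k * r / (1 + (k - 1) * r)
    c(step_up(l1), step_up(u1))
  })
  if (any(!is.finite(ci))) ci <- c(NA_real_, NA_real_)

  list(icc = icc_ak, icc_consistency = icc_ck, ci = ci,
       msr = msr, msc = msc, mse = mse)
}

#' Two-step Bland-Altman agreement analysis
#'
#' Step 1 compares the mean within-pair difference with zero by a paired
#' t-test; step 2 regresses the differences on the pair means to detect
#' proportional bias. Limits of agreement are `bias +/- 1.96 sd(diff)`
#' (sample SD, classic multiplier).
#'
#' @param f1,f2 numeric vectors of per-subject values for each half.
#' @return list with `bias`, `bias_p`, `loa_low`, `loa_high`,
#'   `prop_bias_slope`, `prop_bias_p`, and the per-subject plot data
#'   (`mean`, `diff`).
#' @export
bland_altman <- function(f1, f2) {
  stopifnot(length(f1) == length(f2))
  n <- length(f1)
  if (n < 5L) stop_inadequate_sample("need at least 5 subjects")
  d <- f1 - f2
  m <- (f1 + f2) / 2
  bias <- mean(d)
  sdd <- stats::sd(d)
  bias_p <- if (sdd == 0) {
    if (abs(bias) < .Machine$double.eps^0.5) 1 else 0
  } else {
    stats::t.test(d)$p.value
  }
  if (stats::var(m) > 0 && stats::var(d) > 0) {
    fit <- suppressWarnings(summary(stats::lm(d ~ m)))
    slope <- fit$coefficients["m", "Estimate"]
    slope_p <- fit$coefficients["m", "Pr(>|t|)"]
  } else {
    slope <- 0; slope_p <- NA_real_
  }
  list(bias = bias, bias_p = bias_p,
       loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
       prop_bias_slope = slope, prop_bias_p = slope_p,
       plot_data = data.frame(mean = m, diff = d))
}

icc_verdict <- function(icc) {
  if (icc > 0.90) "excellent"
  else if (icc > 0.80) "good"
  else if (icc > 0.70) "sufficient"
  else "insufficient"
}

default_reliability_metrics <- c("tinn", "lf_hf_fd", "sampen", "dfa_alpha1",
                                 "lf_hf_tf")

#' Split-half reliability table for a cohort of segments
#'
#' For each 300-s segment the two 150-s halves are independently
#' preprocessed and profiled; per metric the battery reports Pearson's r,
#' the Spearman-Brown coefficient, Cronbach's alpha, the average-measures
#' ICC with 95% CI and verdict (`>0.70` sufficient, `>0.80` good, `>0.90`
#' excellent), and the two-step Bland-Altman quantities.
#'
#' @param segments list of usable 300-s [rr_series()] segments, or a
#'   precomputed list of `list(f1 = profile, f2 = profile)` pairs.
#' @param metrics character vector of profile field names.
#' @param cfg a [preprocess_config()].
#' @return data.frame of class `reliability_table`, one row per metric,
#'   with the per-metric Bland-Altman plot data in
#'   `attr(, "plot_data")`.
#' @export
reliability_table <- function(segments,
                              metrics = default_reliability_metrics,
                              cfg = preprocess_config()) {
  if (length(segments) < 5L)
    stop_inadequate_sample("need at least 5 usable segments")
  pairs <- lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    if (inherits(s, "rr_series")) {
      hv <- split_halves(s)
      id <- if (!is.null(s$meta$id)) s$meta$id else paste0("s", i)
      list(f1 = hrv_profile(hv$f1, cfg, id = id, segment = "F1"),
           f2 = hrv_profile(hv$f2, cfg, id = id, segment = "F2"))
    } else s
  })
  rows <- list()
  plot_data <- list()
  for (met in metrics) {
    v1 <- vapply(pairs, function(p) as.numeric(p$f1[[met]]), numeric(1))
    v2 <- vapply(pairs, function(p) as.numeric(p$f2[[met]]), numeric(1))
    ok <- is.finite(v1) & is.finite(v2)
    v1 <- v1[ok]; v2 <- v2[ok]
    if (length(v1) < 5L)
      stop_inadequate_sample(sprintf("metric %s: fewer than 5 usable pairs", met))
    r <- stats::cor(v1, v2)
    icc <- icc_average(v1, v2)
    ba <- bland_altman(v1, v2)
    rows[[met]] <- data.frame(
      metric = met, n = length(v1),
      pearson_r = r,
      rhh = spearman_brown(r),
      cronbach_alpha = cronbach_alpha_2item(v1, v2),
      icc = icc$icc,
      icc_ci_low = icc$ci[1], icc_ci_high = icc$ci[2],
      icc_consistency = icc$icc_consistency,
      bias = ba$bias, bias_p = ba$bias_p,
      loa_low = ba$loa_low, loa_high = ba$loa_high,
      prop_bias_slope = ba$prop_bias_slope,
      verdict = icc_verdict(icc$icc),
      stringsAsFactors = FALSE
    )
    plot_data[[met]] <- ba$plot_data
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "plot_data") <- plot_data
  class(out) <- c("reliability_table", "data.frame")
  out
}
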