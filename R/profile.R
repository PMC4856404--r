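#' Compute a four-domain HRV profile for one segment
#'
#' Runs the full metric battery on a selected segment: ectopic detection
#' and spline correction, then time-domain (mean HR, SDNN, RMSSD, TI,
#' TINN), nonlinear (SampEn, DFA exponents) on the corrected beat-domain
#' series, and frequency/time-frequency metrics (Burg-AR LF/HF, Morlet
#' scalogram LF/HF) on the resampled, wavelet-detrended tachogram. The
#' detrend is applied to the spectral pathway only; beat-domain metrics use
#' the corrected series directly.
#'
#' Metrics whose preconditions a given segment cannot meet (e.g. the
#' long-term DFA exponent on a very short half) are returned as `NA` rather
#' than aborting the profile.
#'
#' @param series an [rr_series()] segment.
#' @param cfg a [preprocess_config()].
#' @param id subject/recording id; default taken from `series$meta$id`.
#' @param segment segment tag (e.g. `"full"`, `"F1"`, `"F2"`).
#' @param ar_order AR model order for the spectral pathway.
#' @return an `hrv_profile` list with the fields of the profile table (see
#'   [write_profile_table()]).
#' @export
hrv_profile <- function(series, cfg = preprocess_config(),
                        id = NULL, segment = "full", ar_order = 16L) {
  stopifnot(inherits(series, "rr_series"))
  if (is.null(id)) id <- if (!is.null(series$meta$id)) series$meta$id else "subject"

  det <- detect_ectopics(series, cfg)
  cor <- correct_ectopics(det, cfg)
  corrected_nn <- cor$intervals  # every corrected interval counts as NN

  maybe <- function(expr) tryCatch(expr, ambuhrv_error = function(e) NA_real_)

  ts <- basic_time_stats(corrected_nn, cfg)
  ti_v <- maybe(triangular_index(corrected_nn))
  tinn_v <- maybe(tinn(corrected_nn))

  se <- maybe(as.numeric(sample_entropy(corrected_nn)))
  al <- tryCatch({
    crv <- dfa(corrected_nn)
    a <- list(
      alpha = maybe(dfa_alphas(crv)$alpha),
      alpha1 = maybe(dfa_alphas(crv)$alpha1),
      alpha2 = maybe(dfa_alphas(crv)$alpha2)
    )
    a
  }, ambuhrv_error = function(e)
    list(alpha = NA_real_, alpha1 = NA_real_, alpha2 = NA_real_))

  spec <- tryCatch({
    tach <- resample_tachogram(cor, cfg)
    dt <- detrend_wavelet(tach, cfg)
    list(ar = maybe_spectrum(dt, ar_order), tf = maybe_tf(dt))
  }, ambuhrv_error = function(e) list(ar = NULL, tf = NULL))

  structure(list(
    id = id, segment = segment,
    mean_hr = ts$mean_hr, sdnn = ts$sdnn, rmssd = ts$rmssd,
    ti = ti_v, tinn = tinn_v,
    vlf_power = if (is.null(spec$ar)) NA_real_ else spec$ar$vlf_power,
    lf_power = if (is.null(spec$ar)) NA_real_ else spec$ar$lf_power,
    hf_power = if (is.null(spec$ar)) NA_real_ else spec$ar$hf_power,
    lf_hf_fd = if (is.null(spec$ar)) NA_real_ else spec$ar$lf_hf,
    lf_nu = if (is.null(spec$ar)) NA_real_ else spec$ar$lf_nu,
    hf_nu = if (is.null(spec$ar)) NA_real_ else spec$ar$hf_nu,
    sampen = se,
    dfa_alpha = al$alpha, dfa_alpha1 = al$alpha1, dfa_alpha2 = al$alpha2,
    lf_hf_tf = if (is.null(spec$tf)) NA_real_ else spec$tf$lf_hf_tf
  ), class = "hrv_profile")
}

maybe_spectrum <- function(dt, ar_order) {
  tryCatch(ar_psd(dt, order = ar_order), ambuhrv_error = function(e) NULL)
}

maybe_tf <- function(dt) {
  tryCatch(cwt_lfhf(dt), ambuhrv_error = function(e) NULL)
}

#' @export
print.hrv_profile <- function(x, ...) {
  cat(sprintf(
    "<hrv_profile> %s [%s]: HR %.1f bpm, SDNN %.1f, TINN %.1f, LF/HF %.2f, SampEn %.2f, DFA a1 %.2f, LF/HF(tf) %.2f\n",
    x$id, x$segment, x$mean_hr, x$sdnn, x$tinn, x$lf_hf_fd, x$sampen,
    x$dfa_alpha1, x$lf_hf_tf))
  invisible(x)
}
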