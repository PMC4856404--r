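#' Preprocessing configuration
#'
#' Defaults follow common short-term HRV practice: a 5-beat running median
#' with a 25% relative deviation threshold for ectopic flagging,
#' physiological bounds of (200, 4000) ms, detrending cutoff 0.0391 Hz,
#' uniform resampling at 4 Hz, and a 25% maximum flagged fraction above
#' which a segment is rejected as too noisy.
#'
#' @param median_window odd number of beats in the running median.
#' @param ectopic_threshold relative deviation from the local median that
#'   flags an interval as ectopic (fraction in (0, 1)).
#' @param physiological_bounds length-2 numeric, plausible RR range (ms);
#'   intervals outside are labelled `artifact`.
#' @param detrend_cutoff_hz cutoff below which the wavelet detrend removes
#'   power (Hz).
#' @param wavelet_family wavelet used by the detrend; `"d4"` (Daubechies,
#'   2 vanishing moments) is implemented.
#' @param resample_hz uniform tachogram sampling rate (Hz); must exceed
#'   twice the upper HF band edge (0.4 Hz).
#' @param max_bad_fraction maximum tolerated flagged (ectopic + artifact)
#'   fraction.
#' @param sd_mode `"population"` or `"sample"` SD for SDNN.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(median_window = 5L,
                              ectopic_threshold = 0.25,
                              physiological_bounds = c(200, 4000),
                              detrend_cutoff_hz = 0.0391,
                              wavelet_family = "d4",
                              resample_hz = 4.0,
                              max_bad_fraction = 0.25,
                              sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  if (median_window %% 2 == 0 || median_window < 3)
    stop_config_error("median_window must be an odd integer >= 3")
  if (ectopic_threshold <= 0 || ectopic_threshold >= 1)
    stop_config_error("ectopic_threshold must lie in (0, 1)")
  if (detrend_cutoff_hz <= 0)
    stop_config_error("detrend_cutoff_hz must be positive")
  if (resample_hz <= 2 * 0.4)
    stop_config_error("resample_hz must exceed twice the upper HF edge (0.8 Hz)")
  structure(list(
    median_window = as.integer(median_window),
    ectopic_threshold = ectopic_threshold,
    physiological_bounds = physiological_bounds,
    detrend_cutoff_hz = detrend_cutoff_hz,
    wavelet_family = wavelet_family,
    resample_hz = resample_hz,
    max_bad_fraction = max_bad_fraction,
    sd_mode = sd_mode
  ), class = "preprocess_config")
}

#' Flag ectopic and artifact intervals
#'
#' Running-median filter: interval k is labelled `ectopic` when it deviates
#' from the local median (window of `median_window` beats centred on k) by
#' more than `ectopic_threshold` times that median. Intervals outside the
#' physiological bounds are labelled `artifact`. Labels are monotone: a
#' previously flagged beat is never relabelled `normal`.
#'
#' @param series an [rr_series()].
#' @param cfg a [preprocess_config()].
#' @return the series with `beat_labels` updated.
#' @export
detect_ectopics <- function(series, cfg = preprocess_config()) {
  stopifnot(inherits(series, "rr_series"))
  x <- series$intervals
  if (length(x) < cfg$median_window)
    stop_inadequate_length(sprintf("need at least %d beats", cfg$median_window))
  med <- stats::runmed(x, cfg$median_window, endrule = "median")
  lab <- series$beat_labels
  ect <- abs(x - med) > cfg$ectopic_threshold * med
  oob <- x <= cfg$physiological_bounds[1] | x >= cfg$physiological_bounds[2]
  lab[lab == "normal" & ect] <- "ectopic"
  lab[lab != "artifact" & oob] <- "artifact"   # bounds override ectopic
  series$beat_labels <- lab
  series
}

#' Correct flagged intervals by cubic-spline interpolation
#'
#' Flagged (`ectopic`/`artifact`) intervals are replaced by a natural cubic
#' spline through the normal intervals, interpolated over beat index (not
#' time, avoiding circularity between onsets and corrected values).
#' Corrected values are clipped to the physiological bounds; normal
#' intervals are untouched; onsets are recomputed.
#'
#' @param series an [rr_series()] with labels from [detect_ectopics()].
#' @param cfg a [preprocess_config()].
#' @return an [rr_series()] with the same number of beats; corrected beat
#'   indices recorded in `meta$corrected`.
#' @export
correct_ectopics <- function(series, cfg = preprocess_config()) {
  stopifnot(inherits(series, "rr_series"))
  bad <- which(series$beat_labels != "normal")
  if (length(bad) == 0L) return(series)
  frac <- length(bad) / n_beats(series)
  if (frac > cfg$max_bad_fraction)
    stop_too_noisy(sprintf(
      "%.1f%% of beats flagged (limit %.0f%%); segment unsuitable for analysis",
      100 * frac, 100 * cfg$max_bad_fraction))
  good <- setdiff(seq_len(n_beats(series)), bad)
  if (length(good) < 4L)
    stop_inadequate_length("need at least 4 normal beats to interpolate")
  sf <- stats::splinefun(good, series$intervals[good], method = "natural")
  x <- series$intervals
  x[bad] <- pmin(pmax(sf(bad), cfg$physiological_bounds[1]),
                 cfg$physiological_bounds[2])
  meta <- series$meta
  meta$corrected <- bad
  rr_series(x, beat_labels = series$beat_labels,
            rhythm_flag = series$rhythm_flag, meta = meta)
}

#' Quality assessment of a selected segment
#'
#' Computes the artifact/ectopic percentage, an outlier percentage
#' (intervals deviating more than 20% from the segment median — a
#' descriptive noise metric, not an exclusion criterion), and the usability
#' verdict: a segment is usable iff it is sinus rhythm, at most
#' `max_bad_fraction` of beats are flagged, and it spans at least 300 s.
#' Verdicts are data, not exceptions.
#'
#' @param series an [rr_series()] (a selected segment). Ectopic detection is
#'   run internally if no beat is flagged yet.
#' @param cfg a [preprocess_config()].
#' @param min_duration_s minimum usable duration (s).
#' @return a `quality_report` list with fields `n_beats`,
#'   `pct_ectopic_or_artifact`, `pct_outlier`, `rhythm_flag`, `usable`,
#'   `exclusion_reason`.
#' @export
assess_quality <- function(series, cfg = preprocess_config(),
                           min_duration_s = 300) {
  stopifnot(inherits(series, "rr_series"))
  flagged <- series
  if (all(series$beat_labels == "normal") &&
      n_beats(series) >= cfg$median_window) {
    flagged <- detect_ectopics(series, cfg)
  }
  n <- n_beats(flagged)
  pct_bad <- 100 * sum(flagged$beat_labels != "normal") / n
  segmed <- stats::median(flagged$intervals)
  pct_out <- 100 * sum(abs(flagged$intervals - segmed) > 0.20 * segmed) / n
  dur <- duration_s(flagged, effective = TRUE)

  reason <- "none"
  if (dur < min_duration_s - 1e-9) {
    reason <- "inadequate_length"
  } else if (flagged$rhythm_flag == "non_sinus") {
    reason <- "non_sinus"
  } else if (pct_bad > 100 * cfg$max_bad_fraction) {
    reason <- "too_noisy"
  }
  structure(list(
    n_beats = n,
    pct_ectopic_or_artifact = pct_bad,
    pct_outlier = pct_out,
    rhythm_flag = flagged$rhythm_flag,
    usable = identical(reason, "none"),
    exclusion_reason = reason
  ), class = "quality_report")
}

#' Serialize a quality report to JSON
#' @param report a `quality_report`.
#' @param path optional output path.
#' @return JSON string, invisibly if written to `path`.
#' @export
quality_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "quality_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Resample a corrected RR series onto a uniform time grid
#'
#' Cubic-spline interpolation of RR (ms) against cumulative onset time,
#' evaluated on the grid `0, 1/fs, 2/fs, ...` covering `[0, last onset]`
#' (length `floor(duration * fs) + 1`). A uniform tachogram is required by
#' the spectral and time-frequency operations.
#'
#' @param series a corrected [rr_series()], at least 4 beats and 60 s.
#' @param cfg a [preprocess_config()]; `resample_hz` sets the grid rate.
#' @return an `rr_tachogram`: list with `t` (s), `rr` (ms), `fs` (Hz).
#' @export
resample_tachogram <- function(series, cfg = preprocess_config()) {
  stopifnot(inherits(series, "rr_series"))
  if (n_beats(series) < 4L) stop_inadequate_length("need at least 4 beats")
  dur <- series$onsets[length(series$onsets)]
  # a window-selected series nominally spans its window; extend the grid to
  # the nominal end (spline extrapolation over less than one beat)
  if (!is.null(series$meta$window))
    dur <- max(dur, series$meta$window[["duration_s"]])
  if (dur < 60) stop_inadequate_length("need at least 60 s of data")
  fs <- cfg$resample_hz
  tt <- seq(0, by = 1 / fs, length.out = floor(dur * fs) + 1L)
  sf <- stats::splinefun(series$onsets, series$intervals, method = "fmm")
  structure(list(t = tt, rr = sf(tt), fs = fs), class = "rr_tachogram")
}

#' @export
print.rr_tachogram <- function(x, ...) {
  cat(sprintf("<rr_tachogram> %d samples at %.2g Hz (%.1f s)\n",
              length(x$t), x$fs, x$t[length(x$t)]))
  invisible(x)
}
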