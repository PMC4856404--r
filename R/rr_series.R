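#' Construct an RR-interval series
#'
#' The central data container of the package: a sequence of beat-to-beat
#' (RR) intervals in milliseconds with cumulative beat onset times in
#' seconds, per-interval beat labels, and a rhythm flag. Intervals are the
#' primary data; `onsets[k]` is the cumulative time `sum(intervals[1:k])/1000`
#' unless explicit onsets are supplied (timestamped device exports).
#'
#' @param intervals numeric vector of RR intervals (ms), all > 0.
#' @param beat_labels character vector, one of `"normal"`, `"ectopic"`,
#'   `"artifact"` per interval. Defaults to all `"normal"`.
#' @param rhythm_flag `"sinus"` or `"non_sinus"`.
#' @param meta named list of metadata (subject id, device tag, selected
#'   window, ...).
#' @param onsets optional explicit cumulative onset times (s), strictly
#'   increasing; default is `cumsum(intervals)/1000`.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(intervals,
                      beat_labels = NULL,
                      rhythm_flag = c("sinus", "non_sinus"),
                      meta = list(),
                      onsets = NULL) {
  rhythm_flag <- match.arg(rhythm_flag)
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L) stop_empty_recording()
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop_domain_error("all RR intervals must be finite and positive")
  if (is.null(onsets)) onsets <- cumsum(intervals) / 1000
  if (length(onsets) != length(intervals))
    stop_domain_error("onsets and intervals must have equal length")
  if (any(diff(onsets) <= 0))
    stop_domain_error("onsets must be strictly increasing")
  if (is.null(beat_labels)) beat_labels <- rep("normal", length(intervals))
  if (!all(beat_labels %in% c("normal", "ectopic", "artifact")))
    stop_domain_error("beat labels must be normal/ectopic/artifact")
  structure(
    list(
      intervals = intervals,
      onsets = as.numeric(onsets),
      beat_labels = beat_labels,
      rhythm_flag = rhythm_flag,
      meta = meta
    ),
    class = "rr_series"
  )
}

#' Number of beats in an RR series
#' @param x an `rr_series`.
#' @return integer beat count.
#' @export
n_beats <- function(x) {
  stopifnot(inherits(x, "rr_series"))
  length(x$intervals)
}

#' Total duration of an RR series
#'
#' Sum of the stored intervals, in seconds. When the series was produced by
#' [select_segment()] the nominal window duration (recorded in `meta$window`)
#' may exceed the beat sum by a fraction of one beat; `effective = TRUE`
#' returns the larger of the two, which is the duration used by length
#' preconditions.
#'
#' @param x an `rr_series`.
#' @param effective if `TRUE`, take the nominal selected-window duration into
#'   account.
#' @return duration in seconds.
#' @export
duration_s <- function(x, effective = FALSE) {
  stopifnot(inherits(x, "rr_series"))
  d <- sum(x$intervals) / 1000
  if (effective && !is.null(x$meta$window))
    d <- max(d, x$meta$window[["duration_s"]])
  d
}

#' Beat start times
#'
#' Onset of the beat that initiates each interval: `onsets - intervals/1000`.
#' Window membership in [select_segment()] is judged on these.
#'
#' @param x an `rr_series`.
#' @return numeric vector of start times (s).
#' @keywords internal
beat_starts <- function(x) x$onsets - x$intervals / 1000

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series> %d beats, %.1f s, rhythm %s; %d flagged\n",
    n_beats(x), duration_s(x), x$rhythm_flag,
    sum(x$beat_labels != "normal")
  ))
  invisible(x)
}

#' Extract normal (NN) intervals
#'
#' @param x an `rr_series`.
#' @return numeric vector of intervals labelled `normal` (ms).
#' @export
nn_intervals <- function(x) {
  stopifnot(inherits(x, "rr_series"))
  x$intervals[x$beat_labels == "normal"]
}
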