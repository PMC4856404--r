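#' @title Condition system
#' @description Internal helpers raising classed conditions so callers can
#'   distinguish data-quality verdicts from programming errors with
#'   `tryCatch(..., hrv_too_noisy = ...)` etc. All classes inherit from
#'   `ambuhrv_error`.
#' @name ambuhrv-conditions
#' @keywords internal
NULL

abort_hrv <- function(class, message, ...) {
  stop(structure(
    list(message = message, call = sys.call(-1), ...),
    class = c(class, "ambuhrv_error", "error", "condition")
  ))
}

stop_empty_recording <- function(msg = "recording contains no beats")
  abort_hrv("hrv_empty_recording", msg)

stop_parse_error <- function(line, msg)
  abort_hrv("hrv_parse_error", sprintf("line %d: %s", line, msg), line = line)

stop_inadequate_length <- function(msg = "series too short for this operation")
  abort_hrv("hrv_inadequate_length", msg)

stop_too_noisy <- function(msg = "more than the allowed fraction of beats is flagged")
  abort_hrv("hrv_too_noisy", msg)

stop_model_order_error <- function(msg) abort_hrv("hrv_model_order_error", msg)

stop_undefined_entropy <- function(msg = "no template matches at length m; entropy undefined")
  abort_hrv("hrv_undefined_entropy", msg)

stop_degenerate_series <- function(msg = "series is constant; fluctuation function is identically zero")
  abort_hrv("hrv_degenerate_series", msg)

stop_insufficient_scales <- function(msg = "fewer than 3 box sizes in the fit range")
  abort_hrv("hrv_insufficient_scales", msg)

stop_domain_error <- function(msg) abort_hrv("hrv_domain_error", msg)

stop_inadequate_sample <- function(msg = "too few subjects for this analysis")
  abort_hrv("hrv_inadequate_sample", msg)

stop_duplicate_key <- function(msg) abort_hrv("hrv_duplicate_key", msg)

stop_spec_error <- function(msg) abort_hrv("hrv_spec_error", msg)

stop_separation_error <- function(msg = "perfect separation detected in logistic fit")
  abort_hrv("hrv_separation_error", msg)

stop_convergence_error <- function(msg = "logistic fit did not converge")
  abort_hrv("hrv_convergence_error", msg)

stop_config_error <- function(msg) abort_hrv("hrv_config_error", msg)
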