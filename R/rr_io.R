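#' Read an RR-interval text export
#'
#' Reads the plain-text RR exports produced by wearable HRV loggers. Two
#' dialects are supported:
#' \describe{
#'   \item{`plain_ms`}{one RR interval (ms) per line; onsets are derived as
#'     the cumulative sum.}
#'   \item{`timestamp_ms`}{two whitespace-separated columns: cumulative beat
#'     onset (s) and RR interval (ms); onsets are taken from column 1.}
#' }
#' Lines starting with `#` are comments; a header comment of the form
#' `# rhythm: non_sinus` sets the rhythm flag (default `sinus`). Other
#' `# key: value` headers are kept in `meta`.
#'
#' @param source path to a file, or a character vector of lines (useful for
#'   in-memory fixtures).
#' @param dialect `"plain_ms"` or `"timestamp_ms"`.
#' @param id optional subject/recording id stored in `meta$id`.
#' @return an [rr_series()].
#' @export
read_rr_text <- function(source, dialect = c("plain_ms", "timestamp_ms"),
                         id = NULL) {
  dialect <- match.arg(dialect)
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  meta <- list(dialect = dialect)
  if (!is.null(id)) meta$id <- id
  rhythm <- "sinus"

  values <- numeric(0)
  onset_col <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#+", "", ln))
      m <- regmatches(body, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.+)$", body))[[1]]
      if (length(m) == 3L) {
        key <- m[[2]]; val <- trimws(m[[3]])
        if (identical(key, "rhythm")) {
          if (!val %in% c("sinus", "non_sinus"))
            stop_parse_error(i, sprintf("unknown rhythm flag '%s'", val))
          rhythm <- val
        } else {
          meta[[key]] <- val
        }
      }
      next
    }
    tok <- strsplit(ln, "[,;[:space:]]+")[[1]]
    expected <- if (dialect == "plain_ms") 1L else 2L
    if (length(tok) != expected)
      stop_parse_error(i, sprintf("expected %d column(s), found %d", expected, length(tok)))
    num <- suppressWarnings(as.numeric(tok))
    if (any(is.na(num)))
      stop_parse_error(i, sprintf("non-numeric token '%s'", tok[which(is.na(num))[1]]))
    if (dialect == "plain_ms") {
      if (num[1] <= 0) stop_parse_error(i, "non-positive RR interval")
      values <- c(values, num[1])
    } else {
      if (num[2] <= 0) stop_parse_error(i, "non-positive RR interval")
      onset_col <- c(onset_col, num[1])
      values <- c(values, num[2])
    }
  }
  if (length(values) == 0L) stop_empty_recording()
  if (dialect == "plain_ms") {
    rr_series(values, rhythm_flag = rhythm, meta = meta)
  } else {
    rr_series(values, rhythm_flag = rhythm, meta = meta, onsets = onset_col)
  }
}

#' Write an RR series as a text export
#'
#' Inverse of [read_rr_text()]; round-trips both dialects.
#'
#' @param series an [rr_series()].
#' @param path output file path; if `NULL` the lines are returned invisibly
#'   instead of written.
#' @param dialect output dialect, see [read_rr_text()].
#' @return the written lines, invisibly.
#' @export
write_rr_text <- function(series, path = NULL,
                          dialect = c("plain_ms", "timestamp_ms")) {
  stopifnot(inherits(series, "rr_series"))
  dialect <- match.arg(dialect)
  hdr <- character(0)
  if (series$rhythm_flag != "sinus")
    hdr <- c(hdr, paste0("# rhythm: ", series$rhythm_flag))
  body <- if (dialect == "plain_ms") {
    format(series$intervals, digits = 15, trim = TRUE, scientific = FALSE)
  } else {
    paste(
      format(series$onsets, digits = 15, trim = TRUE, scientific = FALSE),
      format(series$intervals, digits = 15, trim = TRUE, scientific = FALSE)
    )
  }
  lines <- c(hdr, body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Select a time window from an RR series
#'
#' Returns the intervals whose *start* time falls in the half-open window
#' `[start_s, start_s + duration_s)`. Onsets of the result are re-referenced
#' to the window start (cumulative over the retained intervals). Membership
#' by interval start with a half-open window guarantees that two abutting
#' windows partition the beats with no double counting, and that a
#' `duration_s`-second recording of constant RR contains exactly
#' `duration_s / RR` intervals.
#'
#' @param series an [rr_series()].
#' @param start_s window offset from recording start (s), `>= 0`.
#' @param duration_s window length (s), default 300 (the conventional
#'   short-term segment).
#' @return an [rr_series()] covering the window; `meta$window` records it.
#' @export
select_segment <- function(series, start_s = 0, duration_s = 300) {
  stopifnot(inherits(series, "rr_series"))
  if (start_s < 0 || duration_s <= 0)
    stop_domain_error("window must have start_s >= 0 and duration_s > 0")
  if (duration_s(series, effective = TRUE) < start_s + duration_s - 1e-9)
    stop_inadequate_length(sprintf(
      "recording spans %.1f s, window requires %.1f s",
      duration_s(series, effective = TRUE), start_s + duration_s))
  starts <- beat_starts(series)
  keep <- starts >= start_s - 1e-12 & starts < start_s + duration_s - 1e-12
  if (!any(keep)) stop_inadequate_length("no beats inside the window")
  meta <- series$meta
  meta$window <- c(start_s = start_s, duration_s = duration_s)
  rr_series(series$intervals[keep],
            beat_labels = series$beat_labels[keep],
            rhythm_flag = series$rhythm_flag,
            meta = meta)
}

profile_columns <- c(
  id = "", segment = "",
  mean_hr = "bpm", sdnn = "ms", rmssd = "ms", ti = "", tinn = "ms",
  vlf_power = "ms2", lf_power = "ms2", hf_power = "ms2",
  lf_hf_fd = "", lf_nu = "pct", hf_nu = "pct",
  sampen = "", dfa_alpha = "", dfa_alpha1 = "", dfa_alpha2 = "",
  lf_hf_tf = ""
)

#' Write a table of HRV profiles to CSV
#'
#' One row per subject-segment, fixed column order, units appended to the
#' header (e.g. `sdnn.ms`). Values survive a write/read round trip to at
#' least 12 significant digits.
#'
#' @param profiles a list of [hrv_profile()] results, or a data.frame in
#'   profile-table shape.
#' @param path output CSV path.
#' @return the data.frame written, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  df <- if (is.data.frame(profiles)) profiles else profile_table(profiles)
  if (nrow(df) == 0L) stop_domain_error("no profiles to write")
  key <- paste(df$id, df$segment, sep = "/")
  if (anyDuplicated(key))
    stop_duplicate_key(sprintf("duplicate subject-segment key '%s'",
                               key[duplicated(key)][1]))
  out <- df
  hdr <- names(profile_columns)
  units <- unname(profile_columns)
  names(out) <- ifelse(nzchar(units), paste(hdr, units, sep = "."), hdr)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v)
    ifelse(is.na(v), "", format(v, digits = 15, trim = TRUE, scientific = FALSE)))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(df)
}

#' Assemble a profile table from a list of profiles
#' @param profiles list of [hrv_profile()] objects.
#' @return data.frame with one row per profile in fixed column order.
#' @export
profile_table <- function(profiles) {
  if (length(profiles) == 0L) stop_domain_error("no profiles to tabulate")
  rows <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "hrv_profile"))
    vals <- lapply(names(profile_columns), function(nm) {
      v <- p[[nm]]
      if (is.null(v)) NA else v
    })
    names(vals) <- names(profile_columns)
    as.data.frame(vals, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a profile table written by [write_profile_table()]
#' @param path CSV path.
#' @return data.frame with bare column names (units stripped).
#' @export
read_profile_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- sub("\\.(ms2|ms|bpm|pct)$", "", names(df))
  df
}
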