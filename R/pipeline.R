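#' @title Pipeline orchestration
#' @description End-to-end drivers tying segment selection, quality
#'   control, preprocessing and the four-domain metric battery together,
#'   with exclusion accounting: excluded recordings are data in the run
#'   manifest (with a reason), never silently dropped, so the acquisition
#'   cascade percentages are computable from any run.
#' @name ambuhrv-pipeline
NULL

#' Analyze a set of RR recordings
#'
#' Applies, per file: pre-screening (missing file -> `not_identified`,
#' caller-supplied ineligibility -> `ineligible`), segment selection,
#' quality assessment (`inadequate_length`, `non_sinus`, `too_noisy`),
#' preprocessing and profiling. Unreadable or unparseable files are
#' recorded as `technical` exclusions and the run continues.
#'
#' @param paths character vector of RR text files (named by subject id;
#'   unnamed paths use the base filename).
#' @param cfg a [preprocess_config()].
#' @param segment_start,segment_duration analysis window (s).
#' @param dialect RR text dialect, see [read_rr_text()].
#' @param prescreen optional named character vector mapping subject ids to
#'   a pre-inclusion exclusion reason (e.g. `"ineligible"`).
#' @return a `run_manifest` list: `profiles` (list of [hrv_profile()]),
#'   `quality` (per-subject `quality_report`s), `exclusions` (named reason
#'   per excluded id), `tally` (counts by reason), `n_attempted`,
#'   `n_included` (past pre-inclusion screening), `n_analyzed`, and
#'   `config`.
#' @export
analyze_files <- function(paths, cfg = preprocess_config(),
                          segment_start = 0, segment_duration = 300,
                          dialect = "plain_ms", prescreen = NULL) {
  if (length(paths) < 1L) stop_config_error("at least one input file required")
  ids <- names(paths)
  if (is.null(ids)) ids <- rep(NA_character_, length(paths))
  ids <- ifelse(is.na(ids) | !nzchar(ids),
                sub("\\.[^.]*$", "", basename(paths)), ids)

  profiles <- list()
  quality <- list()
  exclusions <- character(0)

  for (i in seq_along(paths)) {
    id <- ids[[i]]
    if (!is.null(prescreen) && id %in% names(prescreen)) {
      exclusions[[id]] <- unname(prescreen[[id]])
      next
    }
    if (!file.exists(paths[[i]])) {
      exclusions[[id]] <- "not_identified"
      next
    }
    series <- tryCatch(read_rr_text(paths[[i]], dialect = dialect, id = id),
                       ambuhrv_error = function(e) e)
    if (inherits(series, "condition")) {
      exclusions[[id]] <- "technical"
      next
    }
    seg <- tryCatch(select_segment(series, segment_start, segment_duration),
                    hrv_inadequate_length = function(e) e)
    if (inherits(seg, "condition")) {
      exclusions[[id]] <- "inadequate_length"
      next
    }
    qr <- assess_quality(seg, cfg, min_duration_s = segment_duration)
    quality[[id]] <- qr
    if (!qr$usable) {
      exclusions[[id]] <- qr$exclusion_reason
      next
    }
    prof <- tryCatch(hrv_profile(seg, cfg, id = id),
                     ambuhrv_error = function(e) e)
    if (inherits(prof, "condition")) {
      exclusions[[id]] <- "technical"
      next
    }
    profiles[[id]] <- prof
  }

  pre <- c("not_identified", "ineligible", "inadequate_length")
  n_attempted <- length(paths)
  n_included <- n_attempted - sum(exclusions %in% pre)
  tally <- table(factor(exclusions,
                        levels = c("not_identified", "ineligible",
                                   "inadequate_length", "technical",
                                   "non_sinus", "too_noisy")))
  stopifnot(length(profiles) + length(exclusions) == n_attempted)
  structure(list(
    profiles = profiles, quality = quality, exclusions = exclusions,
    tally = as.list(tally),
    n_attempted = n_attempted, n_included = n_included,
    n_analyzed = length(profiles),
    config = unclass(cfg),
    segment = c(start_s = segment_start, duration_s = segment_duration)
  ), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> attempted %d, included %d, analyzed %d\n",
              x$n_attempted, x$n_included, x$n_analyzed))
  tl <- unlist(x$tally)
  tl <- tl[tl > 0]
  if (length(tl))
    cat("  exclusions:", paste(sprintf("%s=%d", names(tl), tl), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a run manifest to JSON
#' @param manifest a `run_manifest`.
#' @param path optional output path.
#' @return JSON string.
#' @export
manifest_json <- function(manifest, path = NULL) {
  stopifnot(inherits(manifest, "run_manifest"))
  payload <- manifest[c("exclusions", "tally", "n_attempted", "n_included",
                        "n_analyzed", "config", "segment")]
  payload$exclusions <- as.list(payload$exclusions)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 10)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Split-half reliability run over RR files
#'
#' Reads and screens the recordings via [analyze_files()] logic, then runs
#' the [reliability_table()] battery on the usable segments.
#'
#' @inheritParams analyze_files
#' @param metrics metric names, see [reliability_table()].
#' @return list with `table` (a `reliability_table`) and `manifest`.
#' @export
run_reliability <- function(paths, cfg = preprocess_config(),
                            metrics = default_reliability_metrics,
                            dialect = "plain_ms") {
  man <- analyze_files(paths, cfg, dialect = dialect)
  usable <- names(man$profiles)
  segments <- lapply(usable, function(id) {
    s <- read_rr_text(paths[[match(id, sub("\\.[^.]*$", "", basename(paths)))]],
                      dialect = dialect, id = id)
    select_segment(s, man$segment[["start_s"]], man$segment[["duration_s"]])
  })
  list(table = reliability_table(segments, metrics, cfg), manifest = man)
}

#' Cohort comparison and outcome model from a profile + covariate table
#'
#' Joins an HRV profile table with a covariate/outcome table on `id`,
#' compares each requested metric between patients and controls with
#' automatic test routing, and fits the backward-elimination logistic
#' outcome model on the metrics reaching univariate p < `p_enter` among
#' patients, with the clinical covariates entered alongside.
#'
#' @param profiles data.frame in profile-table shape (or list of profiles).
#' @param covariates data.frame with columns `id`, `group`, `outcome` and
#'   the clinical covariates.
#' @param metrics HRV metric columns to analyze.
#' @param model_covariates covariates entered in the outcome model.
#' @param p_enter univariate significance threshold gating model entry.
#' @param p_remove backward-elimination removal threshold.
#' @return list with `comparisons` (per-metric test results),
#'   `outcome_univariate`, `model` (a `logistic_model`, or `NULL` when no
#'   metric qualifies), and `n_missing_outcome`.
#' @export
run_cohort <- function(profiles, covariates,
                       metrics = c("tinn", "lf_hf_fd", "sampen",
                                   "dfa_alpha1", "lf_hf_tf"),
                       model_covariates = c("age", "gender", "sbp", "dbp",
                                            "hr", "spo2", "gcs"),
                       p_enter = 0.05, p_remove = 0.10) {
  if (!is.data.frame(profiles)) profiles <- profile_table(profiles)
  if (!is.data.frame(covariates) || nrow(covariates) == 0L)
    stop_config_error("covariate table is empty")
  stopifnot(all(c("id", "group", "outcome") %in% names(covariates)))
  df <- merge(profiles, covariates, by = "id",
              suffixes = c("", ".cov"))

  comparisons <- lapply(metrics, function(m)
    c(list(metric = m), compare_groups(df[[m]], df$group)))
  names(comparisons) <- metrics

  pat <- df[df$group == "patient", , drop = FALSE]
  n_missing <- sum(is.na(pat$outcome))
  pat_out <- pat[!is.na(pat$outcome), , drop = FALSE]
  uni <- lapply(metrics, function(m)
    c(list(metric = m), compare_groups(pat_out[[m]], pat_out$outcome)))
  names(uni) <- metrics

  qualified <- metrics[vapply(uni, function(u) u$p < p_enter, logical(1))]
  model <- NULL
  if (length(qualified)) {
    dat <- pat_out
    dat$outcome_bin <- as.integer(dat$outcome == "unfavorable")
    dat$gender <- factor(dat$gender)
    model <- backward_conditional_logistic(
      dat, "outcome_bin", qualified,
      covariates = intersect(model_covariates, names(dat)),
      p_remove = p_remove)
  }
  list(comparisons = comparisons, outcome_univariate = uni, model = model,
       n_missing_outcome = n_missing)
}

#' Write a synthetic cohort as RR text files
#'
#' Materializes [generate_cohort()] output (signals mode) as one RR text
#' file per subject plus a covariate/outcome CSV, the on-disk interface of
#' [analyze_files()] and [run_cohort()].
#'
#' @param records cohort from [generate_cohort()] with `signals = TRUE`.
#' @param dir output directory (created if needed).
#' @param dialect RR text dialect.
#' @return named character vector of file paths (covariate table path in
#'   attribute `"covariates"`).
#' @export
simulate_cohort_files <- function(records, dir, dialect = "plain_ms") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(records, function(r) {
    stopifnot(!is.null(r$rr))
    p <- file.path(dir, paste0(r$id, ".txt"))
    write_rr_text(r$rr, p, dialect = dialect)
    p
  }, character(1))
  names(paths) <- vapply(records, `[[`, character(1), "id")
  cov <- do.call(rbind, lapply(records, function(r) data.frame(
    id = r$id, group = r$group, outcome = r$outcome,
    age = r$age, gender = r$gender, sbp = r$sbp, dbp = r$dbp,
    spo2 = r$spo2, gcs = r$gcs,
    stringsAsFactors = FALSE)))
  cov_path <- file.path(dir, "covariates.csv")
  utils::write.csv(cov, cov_path, row.names = FALSE)
  attr(paths, "covariates") <- cov_path
  paths
}
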