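#' Automated normality gate
#'
#' Shapiro-Wilk decision used to route downstream tests: `"normal"` when
#' the test p-value exceeds 0.05, `"non_normal"` otherwise. A constant
#' vector is classified `non_normal` (the test itself is undefined there;
#' the degenerate rule keeps the gate total).
#'
#' @param values numeric vector, `n >= 3`.
#' @return `"normal"` or `"non_normal"`.
#' @export
normality_gate <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop_inadequate_sample("need at least 3 values")
  if (stats::var(values) == 0) return("non_normal")
  p <- stats::shapiro.test(values)$p.value
  if (p > 0.05) "normal" else "non_normal"
}

summarize_by_gate <- function(v, gate) {
  if (gate == "normal") {
    sprintf("%.3g (SD %.3g)", mean(v), stats::sd(v))
  } else {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.3g (IQR %.3g-%.3g)", q[2], q[1], q[3])
  }
}

#' Two-group comparison with automatic test selection
#'
#' Continuous variables: Welch t-test when both groups pass the normality
#' gate, Mann-Whitney U otherwise. Categorical variables: Pearson's
#' chi-squared, switching to Fisher's exact test when any expected cell
#' count is below 5. Summaries are mean (SD) or median (IQR) according to
#' the gate.
#'
#' @param values numeric or categorical vector.
#' @param groups two-level factor (or coercible) of the same length.
#' @return list with `test`, `statistic`, `p`, and per-group `summaries`.
#' @export
compare_groups <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop_domain_error("exactly two groups required")
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  split_v <- split(values, groups)
  if (any(vapply(split_v, length, integer(1)) < 3L))
    stop_inadequate_sample("each group needs at least 3 observations")

  if (is.numeric(values)) {
    gates <- vapply(split_v, normality_gate, character(1))
    if (all(gates == "normal")) {
      tt <- stats::t.test(values ~ groups)
      res <- list(test = "t", statistic = unname(tt$statistic), p = tt$p.value)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(values ~ groups))
      res <- list(test = "mann_whitney", statistic = unname(wt$statistic),
                  p = wt$p.value)
    }
    res$summaries <- mapply(summarize_by_gate, split_v, gates)
    res
  } else {
    tab <- table(values, groups)
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts < 5)) {
      ft <- stats::fisher.test(tab)
      list(test = "fisher", statistic = NA_real_, p = ft$p.value,
           summaries = apply(tab, 2, paste, collapse = "/"))
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      list(test = "chisq", statistic = unname(ct$statistic), p = ct$p.value,
           summaries = apply(tab, 2, paste, collapse = "/"))
    }
  }
}

#' Correlation with automatic method selection
#'
#' Pearson when both vectors pass the normality gate, Spearman otherwise.
#'
#' @param x,y paired numeric vectors, `n >= 5`.
#' @return list with `method`, `coefficient`, `p`.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5L) stop_inadequate_sample("need at least 5 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_domain_error("constant vector; correlation undefined")
  method <- if (normality_gate(x) == "normal" && normality_gate(y) == "normal")
    "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(method = method, coefficient = unname(ct$estimate), p = ct$p.value)
}

#' Backward-elimination logistic regression for binary outcome
#'
#' Starts from the full model containing all candidate HRV terms plus the
#' clinical covariates and iteratively removes the term with the largest
#' likelihood-ratio p-value above `p_remove`, refitting after each
#' removal. Reports odds ratios `exp(beta)` with Wald 95% confidence
#' intervals and the ordered removal trace. Rows with missing values among
#' the entered terms are dropped listwise (count reported).
#'
#' @param data data.frame with one row per subject.
#' @param outcome name of the binary outcome column (0/1, logical, or a
#'   two-level factor; the second level / TRUE / 1 is the event).
#' @param candidates character vector of candidate predictor columns.
#' @param covariates character vector of covariate columns (also subject to
#'   elimination, per the backward-over-all-terms convention).
#' @param p_remove removal threshold on the likelihood-ratio p (default
#'   0.10).
#' @return a `logistic_model` list: `retained`, `coefficients`,
#'   `odds_ratios` (data.frame with OR, ci_low, ci_high, p), `removal_trace`,
#'   `n_used`, `n_dropped`, and the final `glm` fit.
#' @export
backward_conditional_logistic <- function(data, outcome, candidates,
                                          covariates = character(0),
                                          p_remove = 0.10) {
  terms_all <- c(candidates, covariates)
  stopifnot(all(c(outcome, terms_all) %in% names(data)))
  y <- data[[outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(as.logical(y) | y == 1)
  df <- data[, terms_all, drop = FALSE]
  df$.y <- y
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (length(unique(df$.y)) < 2L)
    stop_inadequate_sample("outcome has a single level after listwise deletion")
  if (min(table(df$.y)) < 10L)
    warning("fewer than 10 subjects in one outcome group; estimates may be unstable")

  fit_glm <- function(terms) {
    fml <- if (length(terms)) {
      stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    } else {
      stats::as.formula(".y ~ 1")
    }
    fit <- withCallingHandlers(
      stats::glm(fml, family = stats::binomial(), data = df),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          stop_separation_error()
        if (grepl("did not converge", conditionMessage(w)))
          stop_convergence_error()
        invokeRestart("muffleWarning")
      })
    fit
  }

  current <- terms_all
  trace <- list()
  fit <- fit_glm(current)
  repeat {
    if (length(current) == 0L) break
    lrt <- stats::drop1(fit, test = "LRT")
    pvals <- lrt[["Pr(>Chi)"]][-1]
    names(pvals) <- rownames(lrt)[-1]
    worst <- names(pvals)[which.max(pvals)]
    if (max(pvals) <= p_remove) break
    trace[[length(trace) + 1L]] <- list(term = worst, p = max(pvals))
    current <- setdiff(current, worst)
    fit <- fit_glm(current)
  }

  cf <- summary(fit)$coefficients
  terms_kept <- setdiff(rownames(cf), "(Intercept)")
  or_tab <- if (length(terms_kept)) {
    data.frame(
      term = terms_kept,
      or = exp(cf[terms_kept, "Estimate"]),
      ci_low = exp(cf[terms_kept, "Estimate"] - 1.96 * cf[terms_kept, "Std. Error"]),
      ci_high = exp(cf[terms_kept, "Estimate"] + 1.96 * cf[terms_kept, "Std. Error"]),
      p = cf[terms_kept, "Pr(>|z|)"],
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else {
    data.frame(term = character(0), or = numeric(0), ci_low = numeric(0),
               ci_high = numeric(0), p = numeric(0))
  }
  structure(list(
    retained = current,
    coefficients = stats::coef(fit),
    odds_ratios = or_tab,
    removal_trace = trace,
    n_used = nrow(df), n_dropped = n_dropped,
    fit = fit
  ), class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> n=%d (%d dropped), retained: %s\n",
              x$n_used, x$n_dropped,
              if (length(x$retained)) paste(x$retained, collapse = ", ")
              else "(intercept only)"))
  if (nrow(x$odds_ratios)) print(x$odds_ratios, digits = 3)
  invisible(x)
}

#' Serialize a logistic model report to JSON
#' @param model a `logistic_model`.
#' @param path optional output path.
#' @return JSON string.
#' @export
logistic_model_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "logistic_model"))
  payload <- list(
    retained = model$retained,
    odds_ratios = model$odds_ratios,
    removal_trace = model$removal_trace,
    n_used = model$n_used,
    n_dropped = model$n_dropped
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 10)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
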