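test_that("the Shapiro-Wilk gate separates Gaussian from log-normal samples", {
  normals <- vapply(1:20, function(s) {
    set.seed(s); normality_gate(rnorm(40)) == "normal"
  }, logical(1))
  expect_gte(sum(normals), 18)
  skewed <- vapply(1:20, function(s) {
    set.seed(s); normality_gate(exp(rnorm(40, 0, 1.5))) == "non_normal"
  }, logical(1))
  expect_gte(sum(skewed), 18)
  expect_identical(normality_gate(rep(3, 10)), "non_normal")
  expect_error(normality_gate(c(1, 2)), class = "hrv_inadequate_sample")
})

test_that("group comparisons route to the right test and are label-symmetric", {
  set.seed(51)
  v <- rnorm(30)
  same <- compare_groups(c(v, v), rep(c("a", "b"), each = 30))
  expect_gt(same$p, 0.999)

  g <- rep(c("x", "y"), each = 25)
  set.seed(52)
  vals <- c(exp(rnorm(25, 0, 1.2)), exp(rnorm(25, 0.5, 1.2)))
  res <- compare_groups(vals, g)
  expect_identical(res$test, "mann_whitney")
  res_flip <- compare_groups(vals, rev(g))
  expect_equal(res$p, res_flip$p, tolerance = 1e-12)

  # categorical with small expected counts switches to Fisher
  cat_v <- rep(c("m", "f", "m", "m"), times = c(13, 11, 2, 13))
  cat_g <- rep(c("fav", "unf"), times = c(24, 15))
  resc <- compare_groups(cat_v, cat_g)
  expect_identical(resc$test, "fisher")
  oracle <- stats::fisher.test(table(cat_v, cat_g))$p.value
  expect_equal(resc$p, oracle, tolerance = 1e-12)
})

test_that("group separation at published effect size is detectable", {
  # means 1.084 (SD 0.420) vs 1.262 (SD 0.279) at n = 40/47
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    vals <- c(rnorm(40, 1.084, 0.420), rnorm(47, 1.262, 0.279))
    compare_groups(vals, rep(c("patient", "control"), c(40, 47)))$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("correlation routing follows the gate and ranks are respected", {
  set.seed(61)
  x <- rnorm(40)
  expect_equal(correlate(x, x)$coefficient, 1)
  nulls <- vapply(1:20, function(s) {
    set.seed(s)
    abs(correlate(rnorm(40), rnorm(40))$coefficient) < 0.32
  }, logical(1))
  expect_gte(sum(nulls), 18)
  set.seed(62)
  xs <- exp(rnorm(40, 0, 1.3))
  res <- correlate(xs, xs^3)
  expect_identical(res$method, "spearman")
  expect_equal(res$coefficient, 1)
  expect_error(correlate(rep(1, 10), rnorm(10)), class = "hrv_domain_error")
})

test_that("a single binary predictor reproduces the cross-product odds ratio", {
  # 2x2 counts: exposed 30 (12 events), unexposed 50 (10 events)
  df <- data.frame(
    xbin = rep(c(1, 0), c(30, 50)),
    y = c(rep(c(1, 0), c(12, 18)), rep(c(1, 0), c(10, 40)))
  )
  m <- backward_conditional_logistic(df, "y", "xbin", p_remove = 1)
  or_closed <- (12 * 40) / (18 * 10)
  expect_equal(m$odds_ratios$or[m$odds_ratios$term == "xbin"], or_closed,
               tolerance = 1e-6)
})

test_that("pure-noise candidates are eliminated", {
  set.seed(71)
  df <- data.frame(y = rbinom(120, 1, 0.4), n1 = rnorm(120), n2 = rnorm(120),
                   n3 = rnorm(120))
  m <- backward_conditional_logistic(df, "y", c("n1", "n2", "n3"))
  expect_length(m$retained, 0)
  expect_equal(length(m$removal_trace), 3L)
})

test_that("an injected effect on the scaling exponent is recovered", {
  hits <- 0L
  for (i in 1:10) {
    tab <- cohort_table(generate_cohort(400, 2, seed = 900 + i,
                                        signals = FALSE))
    pat <- tab[tab$group == "patient", ]
    pat$y <- as.integer(pat$outcome == "unfavorable")
    pat$gender <- factor(pat$gender)
    m <- backward_conditional_logistic(
      pat, "y", "dfa_alpha1",
      covariates = c("age", "gender", "sbp", "dbp", "hr", "spo2", "gcs"))
    if ("dfa_alpha1" %in% m$retained) {
      row <- m$odds_ratios[m$odds_ratios$term == "dfa_alpha1", ]
      if (row$or < 1 && row$ci_high < 1) hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})

test_that("odds ratios are invariant to affine recoding of other covariates", {
  set.seed(81)
  df <- data.frame(a = rnorm(200), b = rnorm(200))
  df$y <- rbinom(200, 1, plogis(-0.5 + 1.2 * df$a - 0.8 * df$b))
  m1 <- backward_conditional_logistic(df, "y", c("a", "b"), p_remove = 1)
  df2 <- df; df2$b <- 10 * df2$b + 100
  m2 <- backward_conditional_logistic(df2, "y", c("a", "b"), p_remove = 1)
  expect_equal(m1$odds_ratios$or[m1$odds_ratios$term == "a"],
               m2$odds_ratios$or[m2$odds_ratios$term == "a"],
               tolerance = 1e-6)
})

test_that("listwise deletion is counted and degenerate outcomes rejected", {
  set.seed(91)
  df <- data.frame(y = rbinom(40, 1, 0.5), x = rnorm(40))
  df$x[c(3, 17)] <- NA
  m <- suppressWarnings(backward_conditional_logistic(df, "y", "x"))
  expect_equal(m$n_dropped, 2L)
  expect_equal(m$n_used, 38L)
  df_one <- data.frame(y = rep(1, 30), x = rnorm(30))
  expect_error(backward_conditional_logistic(df_one, "y", "x"),
               class = "hrv_inadequate_sample")
})
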