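test_that("time-based halves partition a segment at 150 s", {
  s <- rr_series(rep(1000, 300),
                 meta = list(window = c(start_s = 0, duration_s = 300)))
  h <- split_halves(s)
  expect_equal(n_beats(h$f1), 150L)
  expect_equal(n_beats(h$f2), 150L)
  expect_error(split_halves(rr_series(rep(1000, 200))),
               class = "hrv_inadequate_length")
})

test_that("Spearman-Brown prophecy matches closed-form values and inflates r", {
  expect_equal(round(spearman_brown(0.897), 3), 0.946)
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0), 0)
  expect_error(spearman_brown(-1), class = "hrv_domain_error")
  r <- seq(0, 1, by = 0.05)
  expect_true(all(spearman_brown(r) >= r))
})

test_that("two-item Cronbach alpha matches its variance formula", {
  set.seed(31)
  f1 <- rnorm(40, 10, 3)
  expect_equal(cronbach_alpha_2item(f1, f1), 1)

  f2 <- f1 + rnorm(40, 0, 1)
  oracle <- 2 * (1 - (var(f1) + var(f2)) / var(f1 + f2))
  expect_equal(cronbach_alpha_2item(f1, f2), oracle, tolerance = 1e-12)

  # independent halves: alpha near zero
  set.seed(32)
  a0 <- cronbach_alpha_2item(rnorm(200), rnorm(200))
  expect_lt(abs(a0), 0.15)
  expect_error(cronbach_alpha_2item(rep(1, 10), rep(-1, 10)),
               class = "hrv_domain_error")
})

test_that("average-measures ICC matches the ANOVA decomposition", {
  set.seed(33)
  f1 <- rnorm(30, 50, 10)
  ic1 <- icc_average(f1, f1 + 1e-9 * rnorm(30))
  expect_gt(ic1$icc, 0.999)

  f2 <- f1 + rnorm(30, 0, 25)  # noise swamps the subject variance
  expect_lt(icc_average(f1, f2)$icc, 0.5)

  # hand-computed two-way ANOVA oracle
  g1 <- rnorm(25, 0, 2); g2 <- g1 + rnorm(25, 0.5, 1)
  m <- cbind(g1, g2); n <- nrow(m); k <- 2
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  mse <- (sum((m - grand)^2) - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
  oracle_agreement <- (msr - mse) / (msr + (msc - mse) / n)
  ic <- icc_average(g1, g2)
  expect_equal(ic$icc, oracle_agreement, tolerance = 1e-9)
  expect_equal(ic$icc_consistency, (msr - mse) / msr, tolerance = 1e-9)
  expect_true(ic$ci[1] < ic$icc && ic$icc < ic$ci[2])
  expect_error(icc_average(rep(1, 10), rep(1, 10)), class = "hrv_domain_error")
})

test_that("for two items the consistency ICC equals Cronbach alpha", {
  for (s in 1:5) {
    set.seed(s)
    f1 <- rnorm(20, 5, 2); f2 <- 0.8 * f1 + rnorm(20, 1, 1)
    expect_equal(icc_average(f1, f2)$icc_consistency,
                 cronbach_alpha_2item(f1, f2), tolerance = 1e-9)
  }
})

test_that("Bland-Altman quantifies bias, limits and proportional bias", {
  set.seed(41)
  f1 <- rnorm(30, 100, 15)
  ba <- bland_altman(f1, f1 - 3)
  expect_equal(ba$bias, 3)
  expect_equal(ba$loa_low, ba$loa_high)  # zero-width limits
  expect_equal(ba$prop_bias_slope, 0)

  # symmetric noise: the paired test should rarely reject
  rejections <- vapply(1:20, function(s) {
    set.seed(s)
    g <- rnorm(40); bland_altman(g + rnorm(40, 0, 0.5), g + rnorm(40, 0, 0.5))$bias_p < 0.05
  }, logical(1))
  expect_lte(sum(rejections), 2)

  # proportional bias F2 = 0.9 F1 is detected
  set.seed(43)
  h <- rnorm(60, 100, 20)
  bp <- bland_altman(h, 0.9 * h + rnorm(60, 0, 0.5))
  expect_lt(bp$prop_bias_p, 0.01)

  # limits contain the bias; swapping halves flips its sign, keeps the width
  set.seed(44)
  a <- rnorm(25, 10, 2); b <- a + rnorm(25, 0.4, 0.6)
  b1 <- bland_altman(a, b); b2 <- bland_altman(b, a)
  expect_true(b1$loa_low <= b1$bias && b1$bias <= b1$loa_high)
  expect_equal(b1$bias, -b2$bias)
  expect_equal(b1$loa_high - b1$loa_low, b2$loa_high - b2$loa_low)
  expect_error(bland_altman(1:3, 2:4), class = "hrv_inadequate_sample")
})

test_that("ICC verdicts follow the reliability cut-offs", {
  expect_identical(ambuhrv:::icc_verdict(0.95), "excellent")
  expect_identical(ambuhrv:::icc_verdict(0.85), "good")
  expect_identical(ambuhrv:::icc_verdict(0.71), "sufficient")
  expect_identical(ambuhrv:::icc_verdict(0.70), "insufficient")
  expect_identical(ambuhrv:::icc_verdict(0.30), "insufficient")
})

test_that("the split-half battery judges a stationary cohort reliable", {
  recs <- generate_cohort(40, 2, seed = 7, signals = TRUE)
  segs <- lapply(recs[1:40], function(r) select_segment(r$rr, 0, 300))
  tab <- reliability_table(segs)
  expect_equal(nrow(tab), 5L)
  expect_setequal(tab$metric,
                  c("tinn", "lf_hf_fd", "sampen", "dfa_alpha1", "lf_hf_tf"))
  expect_true(all(tab$icc > 0.70))
  expect_true(all(tab$verdict %in% c("sufficient", "good", "excellent")))
  expect_true(all(abs(tab$cronbach_alpha - tab$icc_consistency) < 1e-9))
  # stationarity: half differences are small relative to the cohort spread
  pd <- attr(tab, "plot_data")
  rel_bias <- vapply(tab$metric, function(m)
    abs(tab$bias[match(m, tab$metric)]) / stats::sd(pd[[m]]$mean), numeric(1))
  expect_true(all(rel_bias < 0.3))
  expect_error(reliability_table(segs[1:3]), class = "hrv_inadequate_sample")
})
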