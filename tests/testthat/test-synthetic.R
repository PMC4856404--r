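test_that("specification invariants are enforced", {
  expect_error(synthetic_spec(a_lf = 0.5, a_hf = 0.4, fractal_weight = 0.2),
               class = "hrv_spec_error")
  expect_error(synthetic_spec(ectopic_rate = 0.6), class = "hrv_spec_error")
  expect_error(synthetic_spec(fractal_alpha = 2), class = "hrv_spec_error")
  expect_error(generate_fractal_series(64, 1.0), class = "hrv_spec_error")
})

test_that("IPFM beat counts and determinism follow the segment specification", {
  const <- generate_rr_ipfm(synthetic_spec(a_lf = 0, a_hf = 0,
                                           fractal_weight = 0, mean_rr = 800))
  expect_lt(max(abs(const$intervals - 800)), 1e-6)

  rr <- generate_rr_ipfm(synthetic_spec(mean_rr = 625, seed = 13))
  expect_lt(abs(n_beats(rr) - 480), 0.05 * 480)

  rr2 <- generate_rr_ipfm(synthetic_spec(mean_rr = 625, seed = 13))
  expect_identical(rr$intervals, rr2$intervals)
})

test_that("an HF-only modulation produces a spectral peak at 0.25 Hz", {
  rr <- generate_rr_ipfm(synthetic_spec(a_lf = 0, a_hf = 0.1,
                                        fractal_weight = 0, seed = 3))
  dt <- detrend_wavelet(resample_tachogram(rr))
  sp <- ar_psd(dt)
  peak <- sp$freqs[which.max(sp$psd)]
  expect_lt(abs(peak - 0.25), 0.02)
  expect_gt(sp$hf_power, sp$lf_power)
})

test_that("fractal generation covers the analytic limits deterministically", {
  lo <- vapply(1:20, function(s)
    dfa_alphas(dfa(generate_fractal_series(480, 0.5, seed = s)))$alpha,
    numeric(1))
  expect_lt(abs(mean(lo) - 0.5), 0.1)
  hi <- vapply(1:20, function(s)
    dfa_alphas(dfa(generate_fractal_series(480, 1.5, seed = s)))$alpha,
    numeric(1))
  expect_lt(abs(mean(hi) - 1.5), 0.15)
  expect_identical(generate_fractal_series(256, 1.0, seed = 4),
                   generate_fractal_series(256, 1.0, seed = 4))
  # generators leave the caller's RNG stream untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_fractal_series(256, 1.0, seed = 9))
  expect_identical(rnorm(1), before)
})

test_that("ectopic injection conserves duration and reports ground truth", {
  rr <- make_clean_segment(seed = 15, mean_rr = 625)
  same <- inject_ectopics(rr, 0, seed = 1)
  expect_identical(same$intervals, rr$intervals)

  inj <- inject_ectopics(rr, 0.018, seed = 2)
  truth <- attr(inj, "truth")
  n_inj <- sum(truth == "ectopic")
  expect_gte(n_inj, 3)
  expect_lte(n_inj, 18)
  expect_lt(abs(sum(inj$intervals) - sum(rr$intervals)), 1e-9)
  # every disturbed beat is followed by its compensatory pause
  expect_true(all(truth[which(truth == "ectopic") + 1L] == "compensatory"))
  expect_error(inject_ectopics(rr, 0.4), class = "hrv_spec_error")
})

test_that("a null cohort yields calibrated p-values", {
  eff <- default_effect_spec()
  eff$patient <- eff$control  # identical groups: no true effect
  pvals <- vapply(1:60, function(s) {
    tab <- cohort_table(generate_cohort(15, 15, effect_spec = eff,
                                        seed = 3000 + s, signals = FALSE))
    compare_groups(tab$dfa_alpha1, tab$group)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("outcome-group effect sizes at published scale give moderate power", {
  eff <- default_effect_spec(outcome = list(
    model = "groups",
    favorable = list(alpha_mean = 1.187, alpha_sd = 0.396, n = 24),
    unfavorable = list(alpha_mean = 0.895, alpha_sd = 0.409, n = 15)))
  hits <- vapply(1:100, function(s) {
    tab <- cohort_table(generate_cohort(39, 2, effect_spec = eff,
                                        seed = 4000 + s, signals = FALSE))
    pat <- tab[tab$group == "patient", ]
    compare_groups(pat$dfa_alpha1, pat$outcome)$p < 0.05
  }, logical(1))
  expect_gte(sum(hits), 40)
})

test_that("cohort generation is reproducible and retains ground truth", {
  r1 <- generate_cohort(5, 5, seed = 77, signals = TRUE)
  r2 <- generate_cohort(5, 5, seed = 77, signals = TRUE)
  expect_identical(cohort_table(r1), cohort_table(r2))
  expect_true(all(vapply(r1, function(r) is.numeric(r$truth$alpha), logical(1))))
  expect_true(all(vapply(r1, function(r)
    r$truth$alpha >= 0.5 && r$truth$alpha <= 1.5, logical(1))))
  outcomes <- vapply(r1[1:5], `[[`, character(1), "outcome")
  expect_true(all(outcomes %in% c("favorable", "unfavorable")))
  expect_true(all(is.na(vapply(r1[6:10], `[[`, character(1), "outcome"))))
})
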