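cfg <- preprocess_config()

test_that("median filter flags the premature beat and only it", {
  x <- rep(800, 10); x[5] <- 400
  d <- detect_ectopics(rr_series(x), cfg)
  expect_equal(which(d$beat_labels == "ectopic"), 5L)
  clean <- detect_ectopics(rr_series(rep(800, 10)), cfg)
  expect_true(all(clean$beat_labels == "normal"))
})

test_that("out-of-bounds intervals are labelled artifact", {
  x <- rep(800, 10); x[4] <- 5000
  d <- detect_ectopics(rr_series(x), cfg)
  expect_identical(d$beat_labels[4], "artifact")
  x2 <- rep(800, 10); x2[4] <- 150
  expect_identical(detect_ectopics(rr_series(x2), cfg)$beat_labels[4], "artifact")
  expect_error(detect_ectopics(rr_series(rep(800, 3)), cfg),
               class = "hrv_inadequate_length")
})

test_that("spline correction replaces flagged beats and nothing else", {
  x <- rep(800, 11); x[6] <- 400
  d <- detect_ectopics(rr_series(x), cfg)
  c1 <- correct_ectopics(d, cfg)
  expect_gt(c1$intervals[6], 790)
  expect_lt(c1$intervals[6], 810)
  expect_identical(c1$intervals[-6], x[-6])   # untouched beats bit-identical
  expect_equal(n_beats(c1), 11L)
  # agreement with a directly fitted natural spline through the neighbours
  good <- setdiff(1:11, 6)
  oracle <- stats::splinefun(good, x[good], method = "natural")(6)
  expect_equal(c1$intervals[6], oracle, tolerance = 1e-12)
})

test_that("correction is the identity without flags and rejects noisy segments", {
  s <- rr_series(rep(800, 10))
  expect_identical(correct_ectopics(s, cfg)$intervals, s$intervals)
  x <- rep(800, 10)
  lab <- rep("normal", 10); lab[c(2, 5, 8)] <- "ectopic"  # 30% flagged
  noisy <- rr_series(x, beat_labels = lab)
  expect_error(correct_ectopics(noisy, cfg), class = "hrv_too_noisy")
})

test_that("resampling reproduces constants, lines and sinusoids", {
  const <- rr_series(rep(800, 400))
  tc <- resample_tachogram(const, cfg)
  expect_equal(length(tc$rr), floor(sum(const$intervals) / 1000 * 4) + 1L)
  expect_true(all(abs(tc$rr - 800) < 1e-9))

  # RR exactly linear in time: cubic splines are exact on polynomials
  n <- 300
  rrs <- 800 + cumsum(rep(0.5, n))
  lin <- rr_series(rrs)
  tl <- resample_tachogram(lin, cfg)
  expected <- stats::approx(lin$onsets, lin$intervals, xout = tl$t, rule = 2)$y
  inside <- tl$t >= lin$onsets[1] & tl$t <= lin$onsets[n]
  expect_lt(max(abs(tl$rr[inside] - expected[inside]) / expected[inside]), 1e-6)

  # sinusoidal modulation recovered within 1% of its amplitude; the series
  # is built so that RR_k equals the modulation evaluated at its own onset
  amp <- 40
  f_mod <- function(t) 800 + amp * sin(2 * pi * 0.1 * t)
  rr_mod <- numeric(400); t_prev <- 0
  for (k in 1:400) {
    tk <- t_prev + 0.8
    for (it in 1:4) tk <- t_prev + f_mod(tk) / 1000  # implicit onset
    rr_mod[k] <- f_mod(tk); t_prev <- tk
  }
  sm <- rr_series(rr_mod)
  ts <- resample_tachogram(sm, cfg)
  truth <- f_mod(ts$t)
  inside <- ts$t >= sm$onsets[1] & ts$t <= sm$onsets[400]
  expect_lt(max(abs(ts$rr[inside] - truth[inside])), 0.01 * amp)

  expect_error(resample_tachogram(rr_series(rep(800, 30)), cfg),
               class = "hrv_inadequate_length")
})

test_that("wavelet transform reconstructs perfectly before band removal", {
  set.seed(42)
  x <- rnorm(256)
  filt <- ambuhrv:::daub4_filters()
  st <- ambuhrv:::dwt_step(x, filt)
  back <- ambuhrv:::idwt_step(st$a, st$d, filt)
  expect_equal(back, x, tolerance = 1e-12)
})

test_that("detrending removes trends and keeps in-band oscillations", {
  tt <- seq(0, 300, by = 0.25)
  sine <- sin(2 * pi * 0.25 * tt)
  ds <- detrend_wavelet(make_tach(sine), cfg)
  expect_lt(sqrt(mean((ds$rr - sine)^2)) / sqrt(mean(sine^2)), 0.05)

  ramp <- seq(0, 100, length.out = length(tt))
  dr <- detrend_wavelet(make_tach(ramp), cfg)
  expect_lt(sqrt(mean(dr$rr^2)) / sqrt(mean(ramp^2)), 0.05)
  expect_lt(abs(mean(dr$rr)), 1)

  dz <- detrend_wavelet(make_tach(numeric(1201)), cfg)
  expect_true(all(dz$rr == 0))

  expect_error(detrend_wavelet(make_tach(numeric(32)), cfg),
               class = "hrv_inadequate_length")
})

test_that("quality verdicts follow the exclusion rules", {
  clean <- select_segment(make_clean_segment(seed = 2), 0, 300)
  q <- assess_quality(clean, cfg)
  expect_true(q$usable)
  expect_identical(q$exclusion_reason, "none")
  expect_lte(q$pct_ectopic_or_artifact, 25)

  ns <- clean; ns$rhythm_flag <- "non_sinus"
  qn <- assess_quality(ns, cfg)
  expect_false(qn$usable)
  expect_identical(qn$exclusion_reason, "non_sinus")

  lab <- rep("normal", n_beats(clean))
  lab[seq_len(ceiling(0.3 * length(lab)))] <- "ectopic"
  noisy <- clean; noisy$beat_labels <- lab
  qo <- assess_quality(noisy, cfg)
  expect_false(qo$usable)
  expect_identical(qo$exclusion_reason, "too_noisy")

  short <- rr_series(rep(800, 100))
  qs <- assess_quality(short, cfg)
  expect_false(qs$usable)
  expect_identical(qs$exclusion_reason, "inadequate_length")

  js <- quality_report_json(q)
  expect_true(jsonlite::validate(js))
})

test_that("detection recovers injected ectopics with few false flags", {
  for (f in c(0.01, 0.05, 0.10)) {
    sens <- numeric(0); fpr <- numeric(0)
    for (i in 1:20) {
      rr <- make_clean_segment(seed = 400 + i)
      inj <- inject_ectopics(rr, f, seed = 500 + i)
      truth <- attr(inj, "truth")
      det <- detect_ectopics(inj, cfg)
      flagged <- det$beat_labels != "normal"
      if (any(truth == "ectopic"))
        sens <- c(sens, mean(flagged[truth == "ectopic"]))
      fpr <- c(fpr, mean(flagged[truth == "normal"]))
    }
    expect_gte(mean(sens), 0.90)
    expect_lte(mean(fpr), 0.02)
  }
})

test_that("detect-correct-detect is a fixed point on injected series", {
  rr <- generate_rr_ipfm(synthetic_spec(seed = 5, ectopic_rate = 0.05,
                                        a_lf = 0.02, a_hf = 0.015,
                                        fractal_weight = 0.05))
  corrected <- correct_ectopics(detect_ectopics(rr, cfg), cfg)
  expect_equal(n_beats(corrected), n_beats(rr))
  refreshed <- corrected
  refreshed$beat_labels <- rep("normal", n_beats(corrected))
  redetect <- detect_ectopics(refreshed, cfg)
  expect_equal(sum(redetect$beat_labels != "normal"), 0L)
})
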