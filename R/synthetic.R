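#' @title Synthetic RR series and cohorts
#' @description Seeded generators that emulate the statistical structure of
#'   short-term in-ambulance RR recordings: 5-minute segments of roughly
#'   370--480 beats with low-frequency (~0.1 Hz) and high-frequency
#'   (~0.25 Hz) rate modulation, a 1/f-like fractal component with a
#'   controllable DFA exponent, injected ectopic beats, and a two-group
#'   cohort whose unfavorable-outcome members have a reduced short-term DFA
#'   exponent, shifted sample entropy, and reduced LF/HF. All generators
#'   are deterministic for a fixed seed; callers' RNG state is preserved.
#' @name ambuhrv-synthetic
NULL

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

sub_seed <- function(seed, k) as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483629)

#' Specification of a synthetic RR segment
#'
#' @param duration_s segment length (s); the study-condition default is 300.
#' @param mean_rr mean RR interval (ms); 625 yields ~480 beats in 300 s,
#'   the average observed during ambulance transportation.
#' @param a_lf,a_hf amplitudes of the 0.1 Hz and 0.25 Hz rate modulations
#'   (dimensionless fractions of the mean rate).
#' @param f_lf,f_hf modulation frequencies (Hz).
#' @param fractal_alpha target DFA scaling exponent of the broadband
#'   component, in `[0.5, 1.5]`.
#' @param fractal_weight amplitude of the fractal component (fraction of
#'   the mean rate).
#' @param ectopic_rate,artifact_rate fractions of beats receiving an
#'   injected premature beat / artifact spike, each in `[0, 0.5]`.
#' @param seed integer RNG seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(duration_s = 300, mean_rr = 625,
                           a_lf = 0.05, a_hf = 0.04,
                           f_lf = 0.10, f_hf = 0.25,
                           fractal_alpha = 1.0, fractal_weight = 0.10,
                           ectopic_rate = 0, artifact_rate = 0,
                           seed = 1L) {
  if (a_lf < 0 || a_hf < 0 || fractal_weight < 0)
    stop_spec_error("modulation amplitudes must be non-negative")
  if (a_lf + a_hf + fractal_weight >= 1)
    stop_spec_error("a_lf + a_hf + fractal_weight must stay below 1 (rate positivity)")
  if (ectopic_rate < 0 || ectopic_rate > 0.5 ||
      artifact_rate < 0 || artifact_rate > 0.5)
    stop_spec_error("injection rates must lie in [0, 0.5]")
  if (fractal_alpha < 0.5 || fractal_alpha > 1.5)
    stop_spec_error("fractal_alpha must lie in [0.5, 1.5]")
  structure(list(duration_s = duration_s, mean_rr = mean_rr,
                 a_lf = a_lf, a_hf = a_hf, f_lf = f_lf, f_hf = f_hf,
                 fractal_alpha = fractal_alpha,
                 fractal_weight = fractal_weight,
                 ectopic_rate = ectopic_rate, artifact_rate = artifact_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a fractal (1/f-like) series with a target DFA exponent
#'
#' Spectral synthesis: Gaussian Fourier coefficients shaped by the
#' power-law spectrum `S(f) ~ f^(1 - 2 alpha)`, inverse-transformed and
#' standardized to zero mean and unit variance. The fitted DFA exponent
#' over boxes 4--64 recovers the target to about +/-0.1.
#'
#' @param n series length (`>= 128`).
#' @param target_alpha target scaling exponent in `[0.5, 1.5]`.
#' @param seed integer RNG seed.
#' @return numeric series of length `n`, unit variance.
#' @export
generate_fractal_series <- function(n, target_alpha, seed = 1L) {
  if (n < 128L) stop_spec_error("n must be at least 128")
  if (target_alpha < 0.5 || target_alpha > 1.5)
    stop_spec_error("target_alpha must lie in [0.5, 1.5]")
  beta <- 2 * target_alpha - 1
  with_seed(seed, {
    nf <- n %/% 2L
    f <- seq_len(nf) / n
    amp <- f^(-beta / 2)
    re <- stats::rnorm(nf); im <- stats::rnorm(nf)
    spec <- complex(real = amp * re, imaginary = amp * im)
    full <- complex(length.out = n)
    full[2:(nf + 1L)] <- spec
    if (n %% 2L == 0L) {
      full[nf + 1L] <- complex(real = amp[nf] * re[nf], imaginary = 0)
      if (nf >= 2L) full[n:(nf + 2L)] <- Conj(spec[1:(nf - 1L)])
    } else {
      full[n:(nf + 2L)] <- Conj(spec[1:nf])
    }
    x <- Re(stats::fft(full, inverse = TRUE)) / n
    as.numeric(scale(x))
  })
}

#' Generate an RR series by integral pulse frequency modulation
#'
#' Beats are emitted whenever the integral of the instantaneous rate
#' `m(t) = (1000/mean_rr) (1 + a_lf sin(2 pi f_lf t) + a_hf sin(2 pi f_hf t)
#' + w z(t))` crosses successive integer thresholds; `z(t)` is a
#' unit-variance fractal process with the requested scaling exponent,
#' generated at beat resolution and interpolated onto the integration
#' grid. Ectopics and artifacts are then injected at the requested rates.
#'
#' @param spec a [synthetic_spec()].
#' @return an [rr_series()]; ground-truth injected labels are attached as
#'   attribute `"truth"`.
#' @export
generate_rr_ipfm <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dt <- 1 / 32
  tt <- seq(0, spec$duration_s, by = dt)
  modul <- spec$a_lf * sin(2 * pi * spec$f_lf * tt) +
    spec$a_hf * sin(2 * pi * spec$f_hf * tt)
  if (spec$fractal_weight > 0) {
    n_z <- max(128L, ceiling(spec$duration_s * 1000 / spec$mean_rr) + 8L)
    z <- generate_fractal_series(n_z, spec$fractal_alpha,
                                 seed = sub_seed(spec$seed, 1L))
    z_t <- seq(0, spec$duration_s, length.out = n_z)
    modul <- modul + spec$fractal_weight *
      stats::approx(z_t, z, xout = tt, rule = 2)$y
  }
  # rare extreme excursions of the unbounded fractal component are
  # saturated: the instantaneous rate stays strictly positive
  modul <- pmax(pmin(modul, 0.95), -0.95)
  rate <- (1000 / spec$mean_rr) * (1 + modul)
  M <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * dt))
  n_beats_total <- floor(M[length(M)])
  beat_times <- numeric(n_beats_total)
  idx <- 1L
  for (b in seq_len(n_beats_total)) {
    while (M[idx + 1L] < b) idx <- idx + 1L
    # linear interpolation of the crossing inside grid cell [idx, idx+1]
    frac <- (b - M[idx]) / (M[idx + 1L] - M[idx])
    beat_times[b] <- tt[idx] + frac * dt
  }
  intervals <- diff(c(0, beat_times)) * 1000
  # the recording nominally spans [0, duration_s]; the last partial beat is
  # not emitted, so the window metadata carries the nominal duration
  series <- rr_series(intervals, meta = list(
    synthetic = TRUE, spec_seed = spec$seed,
    window = c(start_s = 0, duration_s = spec$duration_s)))
  truth <- rep("normal", length(intervals))
  if (spec$ectopic_rate > 0) {
    series <- inject_ectopics(series, spec$ectopic_rate,
                              seed = sub_seed(spec$seed, 2L))
    truth <- attr(series, "truth")
  }
  if (spec$artifact_rate > 0) {
    series <- inject_ectopics(series, spec$artifact_rate,
                              seed = sub_seed(spec$seed, 3L),
                              shorten = 0.15, truth_label = "artifact")
    t2 <- attr(series, "truth")
    truth[t2 != "normal"] <- t2[t2 != "normal"]
  }
  attr(series, "truth") <- truth
  series
}

#' Inject premature (ectopic) beats into an RR series
#'
#' A selected beat `k` is shortened to `shorten * RR_k` and the removed
#' time is added to the following interval (compensatory pause), so the
#' total duration is conserved exactly. Selected positions are
#' non-adjacent. Ground-truth labels are attached as attribute `"truth"`:
#' the disturbed beat carries `truth_label` and the following beat
#' `"compensatory"` (its pause is abnormal as well).
#'
#' @param series an [rr_series()].
#' @param rate fraction of beats to disturb, `<= 0.25`.
#' @param seed integer RNG seed.
#' @param shorten shortening factor for the disturbed beat (0.6 emulates a
#'   premature beat; 0.15 produces an out-of-bounds artifact spike).
#' @param truth_label label recorded for disturbed beats.
#' @return the modified [rr_series()] with attribute `"truth"`.
#' @export
inject_ectopics <- function(series, rate, seed = 1L, shorten = 0.6,
                            truth_label = "ectopic") {
  stopifnot(inherits(series, "rr_series"))
  if (rate < 0 || rate > 0.25) stop_spec_error("rate must lie in [0, 0.25]")
  n <- n_beats(series)
  truth <- rep("normal", n)
  if (rate == 0 || n < 3L) {
    attr(series, "truth") <- truth
    return(series)
  }
  with_seed(seed, {
    cand <- which(stats::runif(n - 1L) < rate)
    keep <- if (length(cand)) cand[c(TRUE, diff(cand) > 1L)] else integer(0)
    x <- series$intervals
    for (k in keep) {
      moved <- (1 - shorten) * x[k]
      x[k] <- shorten * x[k]
      x[k + 1L] <- x[k + 1L] + moved
      truth[k] <- truth_label
      # the compensatory pause is abnormal too; a detector flagging it is
      # right, so it is distinguished from truly normal beats
      if (truth[k + 1L] == "normal") truth[k + 1L] <- "compensatory"
    }
    out <- rr_series(x, beat_labels = series$beat_labels,
                     rhythm_flag = series$rhythm_flag, meta = series$meta)
    attr(out, "truth") <- truth
    out
  })
}

#' Default cohort effect specification
#'
#' Group-level generator parameters anchored to the published summaries of
#' comparable ambulance and control populations: patients at ~97 bpm with
#' a short-term scaling exponent of 1.084 (SD 0.420) and 1.8% ectopics,
#' controls at ~75 bpm with exponent 1.262 (SD 0.279) and 0.63% ectopics,
#' and a logistic outcome model on the true exponent (log-OR -1.5 per
#' unit) yielding roughly 38% unfavorable outcomes among patients.
#'
#' @param outcome outcome model: `list(model = "logistic", intercept,
#'   alpha_coef)` samples the outcome from the subject's true exponent;
#'   `list(model = "groups", favorable = list(alpha_mean, alpha_sd, n),
#'   unfavorable = list(...))` fixes the outcome split and draws exponents
#'   per outcome group.
#' @return an `effect_spec` list with `control`, `patient`, `outcome`.
#' @export
default_effect_spec <- function(outcome = list(model = "logistic",
                                               intercept = 1.16,
                                               alpha_coef = -1.5)) {
  structure(list(
    control = list(alpha_mean = 1.262, alpha_sd = 0.279, mean_hr = 75,
                   hr_sd = 13, a_lf = 0.014, a_hf = 0.008,
                   fractal_weight = 0.028, ectopic_rate = 0.0063,
                   artifact_rate = 0.002, sbp = c(128, 15), dbp = c(78, 10),
                   spo2 = c(98, 1), lf_hf_med = 2.48, lf_hf_tf_med = 2.155,
                   tinn_med = 128.4),
    patient = list(alpha_mean = 1.084, alpha_sd = 0.420, mean_hr = 97,
                   hr_sd = 21, a_lf = 0.010, a_hf = 0.008,
                   fractal_weight = 0.033, ectopic_rate = 0.018,
                   artifact_rate = 0.005, sbp = c(158, 29), dbp = c(90, 17),
                   spo2 = c(96, 2), lf_hf_med = 1.32, lf_hf_tf_med = 1.117,
                   tinn_med = 81.45),
    outcome = outcome
  ), class = "effect_spec")
}

draw_subject_alpha <- function(grp, eff, outcome_known, seed) {
  with_seed(seed, {
    g <- eff[[grp]]
    if (grp == "patient" && identical(eff$outcome$model, "groups")) {
      og <- eff$outcome[[outcome_known]]
      stats::rnorm(1, og$alpha_mean, og$alpha_sd)
    } else {
      stats::rnorm(1, g$alpha_mean, g$alpha_sd)
    }
  })
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

draw_covariates <- function(grp, g, seed) {
  with_seed(seed, {
    age <- clamp(stats::rnorm(1, if (grp == "patient") 69 else 68, 14), 18, 98)
    gender <- sample(c("male", "female"), 1, prob = c(0.525, 0.475))
    sbp <- clamp(stats::rnorm(1, g$sbp[1], g$sbp[2]), 70, 260)
    dbp <- clamp(stats::rnorm(1, g$dbp[1], g$dbp[2]), 40, 160)
    spo2 <- clamp(round(stats::rnorm(1, g$spo2[1], g$spo2[2])), 75, 100)
    gcs <- if (grp == "patient") {
      sample(c(15L, 14L, 13L, 12L, 10L, 8L), 1,
             prob = c(0.66, 0.12, 0.08, 0.06, 0.05, 0.03))
    } else 15L
    glyc <- if (grp == "patient") round(exp(stats::rnorm(1, log(139), 0.35))) else NA
    hx_hypertension <- stats::runif(1) < if (grp == "patient") 0.40 else 0.25
    hx_diabetes <- stats::runif(1) < if (grp == "patient") 0.35 else 0.10
    list(age = age, gender = gender, sbp = sbp, dbp = dbp, spo2 = spo2,
         gcs = gcs, glycaemia = glyc,
         hx_hypertension = hx_hypertension, hx_diabetes = hx_diabetes)
  })
}

# Direct draw of an HRV profile consistent with the subject's true exponent;
# used when RR signal synthesis is not required (signals = FALSE).
draw_profile_direct <- function(id, grp, g, alpha_true, seed) {
  with_seed(seed, {
    hr <- clamp(stats::rnorm(1, g$mean_hr, g$hr_sd), 45, 160)
    a1 <- alpha_true + stats::rnorm(1, 0, 0.08)
    se <- clamp(2.8 - 0.9 * alpha_true + stats::rnorm(1, 0, 0.35), 0.2, 3.5)
    lf_hf <- exp(stats::rnorm(1, log(g$lf_hf_med), 0.8))
    lf_hf_tf <- exp(log(lf_hf) * 0.8 + stats::rnorm(1, log(g$lf_hf_tf_med) * 0.2, 0.4))
    tinn_v <- exp(stats::rnorm(1, log(g$tinn_med), 0.5))
    sdnn_v <- exp(stats::rnorm(1, log(35), 0.4))
    structure(list(
      id = id, segment = "full",
      mean_hr = hr, sdnn = sdnn_v, rmssd = sdnn_v * 0.8,
      ti = tinn_v / 12, tinn = tinn_v,
      vlf_power = NA_real_, lf_power = lf_hf * 100, hf_power = 100,
      lf_hf_fd = lf_hf, lf_nu = 100 * lf_hf / (1 + lf_hf),
      hf_nu = 100 / (1 + lf_hf),
      sampen = se, dfa_alpha = a1 + 0.05, dfa_alpha1 = a1,
      dfa_alpha2 = a1 - 0.05, lf_hf_tf = lf_hf_tf
    ), class = "hrv_profile")
  })
}

#' Generate a synthetic two-group cohort
#'
#' Each subject carries covariates drawn from documented group
#' distributions, a true short-term scaling exponent (retained as ground
#' truth), a binary 30-day outcome (patients only) sampled from the
#' effect specification's outcome model, and either a generated RR series
#' (`signals = TRUE`, for end-to-end pipeline runs) or a directly drawn
#' HRV profile (`signals = FALSE`, for fast statistical-layer studies).
#' Per-subject RNG streams are derived from the master seed, so any
#' subject is reproducible independently of cohort size.
#'
#' @param n_patients,n_controls group sizes (`>= 2`).
#' @param effect_spec an effect specification, see [default_effect_spec()].
#' @param seed master integer seed.
#' @param signals synthesize RR series (`TRUE`) or draw profiles directly.
#' @return list of `subject_record` lists; ground-truth parameters in each
#'   record's `truth` field.
#' @export
generate_cohort <- function(n_patients, n_controls,
                            effect_spec = default_effect_spec(),
                            seed = 1L, signals = TRUE) {
  if (n_patients < 2L || n_controls < 2L)
    stop_spec_error("need at least 2 subjects per group")
  eff <- effect_spec
  outcome_mode <- eff$outcome$model
  groups <- c(rep("patient", n_patients), rep("control", n_controls))

  # in fixed-groups mode, pre-assign patient outcomes
  fixed_outcomes <- NULL
  if (identical(outcome_mode, "groups")) {
    nf <- eff$outcome$favorable$n
    nu <- eff$outcome$unfavorable$n
    if (nf + nu != n_patients)
      stop_spec_error("outcome group sizes must sum to n_patients")
    fixed_outcomes <- c(rep("favorable", nf), rep("unfavorable", nu))
  }

  records <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    grp <- groups[[i]]
    g <- eff[[grp]]
    s0 <- sub_seed(seed, 17L * i)
    outcome_known <- if (grp == "patient" && !is.null(fixed_outcomes))
      fixed_outcomes[[i]] else NA_character_
    alpha_true <- clamp(draw_subject_alpha(grp, eff, outcome_known,
                                           sub_seed(s0, 1L)), 0.5, 1.5)
    cov <- draw_covariates(grp, g, sub_seed(s0, 2L))
    outcome <- if (grp == "control") {
      NA_character_
    } else if (!is.null(fixed_outcomes)) {
      outcome_known
    } else {
      p <- stats::plogis(eff$outcome$intercept +
                           eff$outcome$alpha_coef * alpha_true)
      with_seed(sub_seed(s0, 3L),
                if (stats::runif(1) < p) "unfavorable" else "favorable")
    }
    id <- sprintf("%s%03d", if (grp == "patient") "P" else "C", i)
    if (signals) {
      # per-subject autonomic tone: log-normal scatter of the modulation
      # amplitudes around the group values gives realistic between-subject
      # spread in LF/HF and overall variability
      pars <- with_seed(sub_seed(s0, 4L), list(
        hr = clamp(stats::rnorm(1, g$mean_hr, g$hr_sd), 45, 160),
        a_lf = g$a_lf * exp(stats::rnorm(1, 0, 0.45)),
        a_hf = g$a_hf * exp(stats::rnorm(1, 0, 0.45)),
        w = g$fractal_weight * exp(stats::rnorm(1, 0, 0.50))
      ))
      tot <- pars$a_lf + pars$a_hf + pars$w
      if (tot >= 0.95) {
        sc <- 0.95 / tot
        pars$a_lf <- pars$a_lf * sc; pars$a_hf <- pars$a_hf * sc
        pars$w <- pars$w * sc
      }
      # recordings run slightly longer than the 300 s analysis window, as
      # a transport recording does; segment selection trims them
      spec <- synthetic_spec(
        duration_s = 312, mean_rr = 60000 / pars$hr,
        a_lf = pars$a_lf, a_hf = pars$a_hf,
        fractal_alpha = alpha_true, fractal_weight = pars$w,
        ectopic_rate = g$ectopic_rate, artifact_rate = g$artifact_rate,
        seed = sub_seed(s0, 5L))
      rr <- generate_rr_ipfm(spec)
      rr$meta$id <- id
      payload <- list(rr = rr, profile = NULL)
    } else {
      payload <- list(rr = NULL,
                      profile = draw_profile_direct(id, grp, g, alpha_true,
                                                    sub_seed(s0, 6L)))
    }
    records[[i]] <- structure(c(list(
      id = id, group = grp, outcome = outcome,
      truth = list(alpha = alpha_true)
    ), cov, payload), class = "subject_record")
  }
  records
}

#' Flatten a cohort into an analysis table
#'
#' One row per subject with covariates, outcome, and HRV metrics (from the
#' record's profile; profiles are computed from the RR series on the fly
#' when absent).
#'
#' @param records list of `subject_record`s from [generate_cohort()].
#' @param cfg a [preprocess_config()] (used when profiles must be computed).
#' @return data.frame, one row per subject.
#' @export
cohort_table <- function(records, cfg = preprocess_config()) {
  rows <- lapply(records, function(r) {
    prof <- r$profile
    if (is.null(prof)) {
      stopifnot(!is.null(r$rr))
      prof <- hrv_profile(r$rr, cfg, id = r$id)
    }
    data.frame(
      id = r$id, group = r$group, outcome = r$outcome,
      age = r$age, gender = r$gender, sbp = r$sbp, dbp = r$dbp,
      hr = prof$mean_hr, spo2 = r$spo2, gcs = r$gcs,
      glycaemia = if (is.null(r$glycaemia) || is.na(r$glycaemia)) NA_real_ else r$glycaemia,
      hx_hypertension = r$hx_hypertension, hx_diabetes = r$hx_diabetes,
      tinn = prof$tinn, lf_hf_fd = prof$lf_hf_fd, sampen = prof$sampen,
      dfa_alpha1 = prof$dfa_alpha1, lf_hf_tf = prof$lf_hf_tf,
      alpha_true = r$truth$alpha,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
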