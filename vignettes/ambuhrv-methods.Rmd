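---
title: "Methods: short-term HRV analysis for in-ambulance recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: short-term HRV analysis for in-ambulance recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambuhrv)
```

## Scope and data model

`ambuhrv` analyses short (5-minute) RR-interval series of the kind exported
by wearable single- or two-lead ECG loggers used during emergency ambulance
transportation. The package starts from an annotated RR series, not from raw
ECG: R-peak detection and rhythm classification are upstream concerns, and a
recording's sinus/non-sinus status arrives as a flag in the file header.

The central container is the `rr_series`: intervals in milliseconds,
cumulative onset times in seconds (`onsets[k] = sum(intervals[1:k]) / 1000`),
per-beat labels (`normal` / `ectopic` / `artifact`) and the rhythm flag.
Millisecond intervals and second-valued times are used throughout; the
conversion constant appears in exactly one place per operation.

### Window membership

Segment selection keeps the intervals whose *start* time lies in the
half-open window `[start, start + duration)`. Two conventions were on the
table (membership by interval end versus by interval start); membership by
start is the one under which a `D`-second recording of constant RR `r`
contains exactly `D / r` intervals — e.g. 480 intervals of 625 ms in a
300-second window — and under which two abutting windows partition the beats
with no loss or double counting. The latter property matters because the
split-half reliability analysis cuts the same segment at 150 s: the
conventional labelling of such halves as "0–150 s / 151–300 s" is realized
here as the contiguous half-open pair `[0, 150)` / `[150, 300)`, so no beat
falls into a one-second gap.

A window-selected (or synthetically generated) series carries its nominal
window duration in `meta$window`; length preconditions use the larger of the
beat sum and this nominal duration, because the last beat of a recording
rarely ends exactly on the window boundary.

## Preprocessing

Ectopic detection uses a running median of 5 beats: interval `k` is flagged
when it deviates from the local median by more than 25% of that median.
Both values are conventional for short-term HRV and are exposed in
`preprocess_config()`; intervals outside (200, 4000) ms are labelled
artifacts outright. Flagged intervals are replaced by a natural cubic spline
through the normal intervals, interpolated over *beat index* rather than
time: interpolating over time would make corrected intervals depend on
onsets that themselves change with the correction. A segment in which more
than 25% of beats are flagged is rejected as too noisy rather than
corrected.

Quality verdicts are data, not exceptions: `assess_quality()` returns a
report with the flagged percentage, an outlier percentage (intervals more
than 20% from the segment median — a descriptive metric only, never an
exclusion criterion), and one of the exclusion reasons
(`inadequate_length`, `non_sinus`, `too_noisy`, or `none`). The pipeline
driver adds the pre-inclusion reasons `not_identified` and `ineligible`, so
a whole acquisition campaign's exclusion cascade can be tabulated from the
run manifest.

Spectral and time-frequency analysis require a uniform tachogram: the
corrected series is cubic-spline resampled at 4 Hz, comfortably above twice
the upper HF edge (0.4 Hz), then detrended by zeroing the lowest band of an
orthogonal Daubechies (D4) decomposition. The decomposition depth is chosen
so the removed band lies within [0, 0.0391] Hz — at 4 Hz this is depth 6,
band [0, 0.03125] Hz. D4 has two vanishing moments, so linear trends live
almost entirely in the removed approximation; reflection padding at both
ends suppresses the boundary leakage that periodic transforms otherwise
produce on non-stationary signals. Whether detrending should also precede
the time-domain and nonlinear metrics is genuinely ambiguous in practice;
here the detrended series feeds only the spectral pathway, while
beat-domain metrics (time-domain, SampEn, DFA) use the corrected series
directly — DFA in particular performs its own per-box detrending.

## The metric battery

**Time domain.** Mean HR (`60000 / mean(NN)`), SDNN (population SD by
default; switchable), RMSSD, and the geometric pair: the triangular index
(total beat count over the modal bin count of the NN histogram) and TINN
(the base width `M − N` of the least-squares triangle fitted to the
histogram, found by exhaustive search over bin positions with
`N < mode < M`). The histogram uses the conventional 1/128 s = 7.8125 ms
bins aligned to multiples of the bin width. A single-bin histogram has no
meaningful triangle; TINN is defined there as one bin width so the metric
is total.

**Frequency domain.** The tachogram's PSD is estimated parametrically by a
Burg autoregressive model of order 16 (a common short-term default; the
order is a parameter) and nonparametrically by a Hann-windowed Welch
periodogram that serves as a cross-check — the two must agree on smooth
spectra, and the Welch integral must reproduce the signal variance
(Parseval), both of which are tested. Band powers integrate the PSD over
VLF [0.0033, 0.04), LF [0.04, 0.15) and HF [0.15, 0.4) Hz. The LF/HF ratio
uses absolute powers; `lf_nu`/`hf_nu` normalized units are reported as
well. An LF/HF above 1 is conventionally read as sympathetic dominance.
VLF is reported but feeds nothing downstream: it is not interpretable on
5-minute records.

**Nonlinear.** Sample entropy with `m = 2` and `r = 0.2 × SD` of the series
(neither is standardized in the source literature for this setting; both
are parameters), computed with Chebyshev distance, self-matches excluded,
and the same template start set for lengths `m` and `m + 1` — the
convention under which a constant series has entropy exactly 0. Detrended
fluctuation analysis integrates the mean-centred series, removes a
least-squares line per non-overlapping box (forward boxes only, tail
remainder dropped) and fits `log10 F(n)` on `log10 n` over boxes 4–64
(overall α), 4–16 (α1) and 16–64 (α2). On halves too short for 64-beat
boxes, the box list is clipped to `n/4` and α2 uses what remains.

**Time-frequency.** A Morlet (centre frequency 6) continuous wavelet
transform on 48 log-spaced scales covering 0.04–0.4 Hz. Band powers
integrate the scalogram over scale with the `ds/s²` measure, under which a
pure tone contributes the same band power wherever it sits — without this
weighting the LF/HF ratio would be biased by the scale-dependent response
of the wavelet. The summary ratio is the ratio of time-averaged band
powers, not the average of instantaneous ratios: instantaneous HF power
passes near zero regularly and would otherwise inject unbounded terms. The
per-time ratio time course is retained for inspection. Time averages
respect the cone of influence (e-folding time `sqrt(2) × scale` from each
edge), falling back to the full record at scales where nothing survives.

## Split-half reliability

`reliability_table()` profiles the two 150-s halves of each subject's
segment independently and reports, per metric: Pearson's r between halves,
the Spearman–Brown prophecy `rhh = 2r / (1 + r)`, Cronbach's α (two-item
form), the two-way random-effects average-measures ICC, and the two-step
Bland–Altman quantities (bias with paired-t p; limits of agreement
`bias ± 1.96 SD(diff)` with the classic 1.96 multiplier; proportional-bias
slope of differences on pair means). Verdicts follow the usual cut-offs:
ICC > 0.70 sufficient, > 0.80 good, > 0.90 excellent.

Two ICC forms exist for "average measures": absolute agreement
(`(MSR − MSE) / (MSR + (MSC − MSE)/n)`) and consistency
(`(MSR − MSE)/MSR`). The consistency form equals Cronbach's α exactly for
two items — a published reliability table in this field shows ICC and α
columns that are close but not equal, which identifies the absolute
agreement form as the reported ICC. Agreement is therefore the primary
form here, with the consistency value reported alongside (and its identity
with α unit-tested). Confidence intervals use the F-based interval for the
single-measure agreement ICC with Satterthwaite degrees of freedom, stepped
up to average measures by the Spearman–Brown relation.

## Cohort statistics and outcome model

Variables are routed by an automated Shapiro–Wilk gate (p > 0.05 counts as
normal; constant vectors are classed non-normal so the gate is total):
Welch t-test or Mann–Whitney U for continuous comparisons, Pearson or
Spearman for correlations, and χ² for categorical tables with an automatic
switch to Fisher's exact test when any expected cell is below 5.

The outcome model is a backward-elimination logistic regression: HRV
metrics reaching univariate p < 0.05 enter together with the clinical
covariates (age, gender, SBP, DBP, HR, SpO₂, GCS); the term with the
largest likelihood-ratio p above `p_remove = 0.10` is removed and the model
refitted until all remaining terms fall below the threshold.
Likelihood-ratio removal tests are used as the open, reproducible
approximation of "conditional" stepwise criteria implemented in commercial
packages (which use a score-based shortcut); the removal threshold matches
that lineage's default and is a parameter. All candidates enter
simultaneously by default. Rows with missing values among entered terms are
dropped listwise, with the count reported. Odds ratios are `exp(β)` with
Wald 95% intervals; perfect separation and non-convergence raise classed
errors rather than returning silently absurd estimates.

## The synthetic generator

Because no recordings of this kind are publicly deposited, the package
ships a generator whose defaults emulate the documented study conditions,
so every stage is testable without any download.

Beats come from an integral pulse frequency modulation (IPFM) model: a beat
is emitted each time the integral of the instantaneous rate
`m(t) = (1000/RRmean) (1 + a_lf sin(2π·0.1t) + a_hf sin(2π·0.25t) + w·z(t))`
crosses an integer. IPFM is preferred over adding noise directly to RR
values because it produces physiologically ordered beats and a clean
mapping from modulation frequencies to spectral bands. `z(t)` is a
unit-variance fractal process synthesized in the frequency domain with
power-law spectrum `S(f) ∝ f^(1−2α)`, giving a controllable DFA exponent
(recovery to ±0.1 is part of the test suite); it is generated at beat
resolution and interpolated onto the 1/32-s integration grid. Extreme
excursions of the unbounded fractal component are clipped at ±0.95 of the
mean rate so the rate stays positive. Ectopics are injected by shortening a
beat to 0.6 of its value and adding the remainder to the next interval — a
conventional premature-beat-plus-compensatory-pause shape that conserves
total duration exactly; ground truth labels both the premature beat and its
compensatory successor. Artifacts use the same mechanism with a 0.15
shortening factor, which lands below the 200 ms physiological bound.

Cohort defaults are anchored to the published group summaries of the
motivating setting: patients at ~97 bpm (≈480 beats per 5-minute segment)
with 1.8% ectopics and short-term exponent 1.084 (SD 0.420), controls at
~75 bpm (≈375 beats) with 0.63% ectopics and exponent 1.262 (SD 0.279),
SBP 158 (29) mmHg, LF/HF medians near 1.3 (patients) and 2.5 (controls).
Per-subject modulation amplitudes get log-normal scatter (log-SD 0.45 for
the sinusoidal amplitudes, 0.50 for the fractal weight) — chosen so the
cohort's TINN quartiles span roughly the published interquartile ranges
(≈55–135 ms in patients); without between-subject spread, split-half
reliability of any metric would be undefined. Recordings run 312 s so that
selecting the first 300 s from a written file behaves as it does with real
device exports, whose recordings outlast the analysis window. The binary
30-day outcome is sampled from a logistic model on the subject's true
exponent (default log-OR −1.5 per unit, intercept 1.16, yielding ≈38%
unfavorable outcomes); an alternative `groups` mode fixes the outcome split
and draws exponents per outcome group, which is the natural way to emulate
a published favorable/unfavorable table directly. Ground truth (the true
exponent) is retained in every record for recovery tests.

`generate_cohort(..., signals = TRUE)` attaches a full RR series per
subject; `signals = FALSE` draws the HRV metrics directly from the group
distributions (with SampEn tied negatively to the exponent, as observed),
which is the right tool for statistical-layer studies such as the logistic
recovery experiment at n = 400 × 100 replicates, where synthesizing 40 000
RR series would add nothing but runtime.

What the generator does *not* emulate: real transport vibration artifacts
(its artifacts are idealized spikes), respiratory frequency drift (HF is a
fixed 0.25 Hz tone), circadian or posture effects, and atrial fibrillation
(non-sinus recordings are emulated by flag, not by waveform). Passing tests
on synthetic cohorts therefore demonstrates correctness of the estimators
and pipeline under controlled conditions, not clinical validity on real
ambulance data.

## Numerical choices and degenerate inputs

* Tachogram grid: `floor(duration × 4 Hz) + 1` points from 0; spline
  extrapolation past the last beat is bounded by one beat.
* The AR spectrum is evaluated on a 1025-point grid over [0, 2] Hz; band
  powers integrate by the trapezoid rule. A zero-variance input returns
  zero powers rather than an error from the AR fit.
* SampEn returns `+Inf` with a `degenerate` attribute when no
  `(m+1)`-template matches exist, and a classed error when even the
  `m`-templates fail to match.
* DFA refuses constant input (`F ≡ 0` carries no scaling information), and
  exponent fits require at least 3 box sizes per range.
* The TINN search and the triangular index require ≥ 20 beats; SampEn ≥ 50
  (relaxable for validation exercises); DFA ≥ 100; AR ≥ 10 × order samples;
  the CWT ≥ 150 s.
* All generators restore the caller's RNG state; per-subject streams are
  derived from the master seed by an affine hash, so any subject is
  reproducible independently of cohort size.

## Problem sizes in the test suite

The suite exercises the pipeline at the study's own scale: reliability on a
40-subject synthetic cohort, end-to-end determinism on 87 subjects
(40 patients + 47 controls), detection sensitivity over 20 replicates per
ectopic rate, DFA limits over 20 replicates of 480 beats, and logistic
recovery over 100 replicates of 400 subjects in profile-only mode. These
sizes keep a full run in the low minutes on a single core while leaving
each statistical check enough replicates to be stable.

## Known limitations

* TINN on 150-s halves is intrinsically noisy (few hundred beats per
  histogram); the literature itself flags TINN as fragile in short-term
  registrations. The estimator here is the plain least-squares definition,
  deliberately without smoothing.
* The measured short-term exponent of an IPFM subject compresses toward the
  middle of the target range (sinusoidal modulation and ectopic correction
  both perturb small-scale fluctuations), so end-to-end group differences
  in α1 are somewhat attenuated relative to the generator's targets; the
  statistical-layer tests therefore use profile-only mode where the printed
  effect sizes are to be reproduced exactly.
* The backward-elimination trace mimics, but cannot be guaranteed identical
  to, the score-test-based "conditional" method of the commercial
  implementation it approximates.
* No Lomb–Scargle pathway: spectra are computed on the resampled tachogram
  only.
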