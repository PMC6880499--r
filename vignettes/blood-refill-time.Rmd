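---
title: "Quantifying blood refill time from fingertip photoplethysmography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying blood refill time from fingertip photoplethysmography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refillr)
```

## The measurement problem

Capillary refill time (CRT) — the seconds it takes a blanched fingertip to
regain its colour — is a bedside proxy for peripheral perfusion, but a human
watching skin colour with a chronometer is a noisy instrument. The
device-based alternative quantified here records transmitted infrared light
(940 nm) through the fingertip at 16-ms resolution. Compressing the
fingertip squeezes haemoglobin — the dominant absorber — out of the tissue,
so transmitted intensity rises; on release, blood refills the capillary bed
and intensity relaxes back toward its pre-compression level. The **blood
refill time (BRT)** is the time for that optical recovery to complete 90%
of its return.

## The model

The recovery phase is modelled as an exponential decay,

$$I(t) = B + A\,e^{-t/\tau},$$

with release at $t = 0$: $A$ is the intensity elevation still present at
release (device units), $\tau$ the recovery time constant (seconds), and $B$
the recovered asymptote. Least squares over the recovery segment estimates
all three. On the fitted curve the drop from $B + A$ to $B$ is 90% complete
when $A e^{-t/\tau} = 0.1 A$, so

$$\mathrm{BRT} = \tau \ln 10 \approx 2.303\,\tau.$$

Three modelling choices deserve comment:

* **90% return is evaluated on the fitted curve, not the raw signal.** A
  raw-signal crossing of the 90% level is at the mercy of cardiac ripple and
  noise near the threshold; the fitted-curve rule is deterministic and gives
  the closed form above. The device's internal convention is not published
  in detail, so this is a documented package choice rather than verified
  hardware behaviour.
* **The asymptote $B$ is fitted, not pinned to the pre-compression
  baseline.** Post-release hyperaemia can overshoot the original level; the
  baseline estimate seeds quality checks (polarity) but does not constrain
  the fit.
* **$t = 0$ is the first sample at or after the release marker.** The
  protocol gives no sub-sample convention; aligning to the sample grid keeps
  results bit-reproducible. Since a time shift is absorbed by $A$ without
  touching $\tau$, BRT is unaffected.

## Fitting: separable least squares

For fixed $\tau$ the model is linear in $(A, B)$, so the inner problem has a
closed-form solution and the whole fit reduces to a one-dimensional search
over $\tau$. `fit_exponential()` scans a 50-point log-spaced grid over
$\tau \in [0.05, 60]$ s (bounds comfortably bracketing physiological refill
times), then refines the best cell by Brent minimisation at $10^{-6}$
relative tolerance. No starting values are needed and the search cannot be
trapped far from the global optimum, which the test suite confirms against a
10,000-point exhaustive grid. A $\tau$ pinned at a search bound or an
amplitude indistinguishable from zero raises `no_convergence`;
$R^2 < 0.5$ raises the non-fatal `low_r_squared` flag. The fatal/warning
split mirrors clinical usability: a value is returned whenever the optimiser
converges, but dubious fits are marked.

## The processing pipeline

`measure_brt()` composes the stages; each is exported and testable alone.

1. **Window detection.** Beep markers, when present, pass through
   unchanged. Otherwise the start is the onset of the largest sustained rise
   (the 0.5-s-smoothed trace exceeding the pre-compression baseline by 5
   ripple SDs for at least 1 s, refined to the first raw sample above
   threshold because a centred average anticipates a ramp), and the release
   is the subsequent steepest raw fall. Auto-detection is a convenience:
   the protocol assumes markers.
2. **Baseline.** Median intensity over the 2 s before compression — the
   median resists pulsatile ripple, and 2 s covers at least two cardiac
   cycles at rest while fitting inside the protocol's timing.
3. **Recovery extraction.** Up to 15 s after release; fewer than 20 samples
   is fatal (`short_segment`). A release level below baseline flags
   inverted polarity.
4. **Pulsation smoothing (on by default).** A 0.5-s centred moving average
   sits near one cardiac cycle and attenuates the superimposed pulsatile
   ripple with minimal bias for $\tau \ge 0.5$ s. The moving average of an
   exponential keeps the same $\tau$ in the window interior (only the
   amplitude is rescaled), but the edge-truncated samples are biased —
   so half a window is trimmed from each end before fitting. That trim is
   why the noise-free closed-form property holds to numerical precision
   rather than merely approximately.
5. **Fit and report.** BRT $= \tau \ln 10$, with flags attached.

Per protocol each subject is measured three times and `average_repeats()`
takes the arithmetic mean, dropping fatally flagged trials with a warning
(the mean-of-survivors rule is a package choice; the study does not state
how failed trials were handled).

## The synthetic world

No patient recordings are publicly deposited, so the package carries a
simulator with known ground truth.

`simulate_waveform()` builds: baseline (default 500 device units) + linear
drift (0.2 units/s) + compression profile (0.3-s linear ramp to
baseline + 100, plateau through the 5-s compression, then
$100\,e^{-t/\tau}$ after release) + cardiac sinusoid (amplitude 5, i.e. 5%
of the compression rise, at 75 bpm) + Gaussian noise (SD 1, 1% of the
rise), sampled every 16 ms for 30 s. The ramp exists because an
instantaneous step is unphysical and breaks derivative-based detection; its
length, the pulse/noise levels, the heart rate and the drift are free
choices fixed once at values a clean bedside recording would show. The
ground truth is $\tau \ln 10$ by construction.

`simulate_cohort()` emulates the 30-subject emergency-department cohort:
admission is Bernoulli(0.4); within each admission group the true
(CRT, BRT) pair is bivariate lognormal, moment-matched on the log scale to
the published group means and SDs (CRT 2.35 ± 0.97 admitted / 1.65 ± 0.47
discharged; BRT 4.69 ± 3.14 / 3.35 ± 2.23 s) with the log-scale correlation
solved so the natural-scale correlation hits the 0.72 target. Lognormal
marginals are the right family: refill times are positive and right-skewed
(the published BRT range 0.96–11.97 s around a mean of 3.88 implies skew),
and the construction builds in the observed proportional bias — BRT longer
and more dispersed than CRT. Triplicates multiply the true value by
lognormal noise with CV 0.15.

What the simulator does **not** emulate: motion artefact, sensor
repositioning, vasomotor waves, optical path physics, or any dependence of
measurement quality on perfusion status. A green round-trip test therefore
establishes that the estimator recovers known exponential recoveries under
stated noise — not that the device is accurate in patients.

One calibration caveat: with CV 0.15 the simulated intraclass correlations
land around 0.85–0.92, above the published 0.72–0.79 single-measure band;
matching that band would need CV near 0.25–0.30. The default stays at 0.15
as the stated world, and published ICCs are treated as qualitative context,
not reproduction targets.

## Agreement and diagnostic statistics

* **Pearson correlation** with the two-sided $t$-transform p-value.
* **Bland–Altman**: differences vs pairwise averages; bias, SD of
  differences, limits of agreement at the conventional ±1.96 SD (no
  small-sample $t$ correction). Proportional bias — differences growing
  with magnitude — is tested by the OLS slope of differences on averages
  with a two-sided $t$-test, the standard extension when the pattern is
  asserted rather than formally tested.
* **ICC**: ANOVA mean squares give Shrout–Fleiss ICC(1,1)/ICC(1,k)
  (one-way random, the default: a single rater re-measures each subject and
  repeats share no ordering factor) or ICC(2,1)/ICC(2,k) (two-way random;
  note SPSS's historical default is two-way mixed, so software-reported
  values may correspond to either). Confidence intervals come from the
  exact F formulas (one-way) and the Satterthwaite-style approximation
  (two-way); single and average forms obey the Spearman–Brown identity
  exactly.
* **ROC/AUC**: empirical threshold sweep; AUC is the Mann–Whitney statistic
  with ties counted ½, identical to the trapezoidal area over the curve;
  the 95% interval uses the DeLong placement-value variance (the standard
  nonparametric choice; the original analysis software does not name its
  method). The optimal cutoff is the operating point nearest the (0, 1)
  corner, ties broken toward higher sensitivity then lower threshold, and
  is reported as the midpoint between the straddling distinct scores so the
  value does not collide with an observation.
* **2×2 metrics** use strict `>` positivity (matching "over the cutoff"
  vs "at or below" phrasing; the CRT abnormality rule is likewise a strict
  3-s exceedance). Display values round to one decimal percent, %CV to the
  nearest integer, matching conventional reporting precision; exact
  fractions are retained internally.

A deliberate non-reproduction: the published discharged-CRT %CV of 29%
cannot be recovered from the printed rounded inputs (100·0.47/1.65 = 28.5),
so it is excluded from the checks; the other three %CV values reproduce.

## Numerical and degenerate-input behaviour

Fits are invariant to intensity scaling and shifts (both absorbed by
$(A, B)$), and resampling the same curve at 8 vs 16 ms moves noise-free BRT
by far less than 0.5%. Constant segments yield $A \approx 0$ with
`no_convergence` rather than an arbitrary $\tau$. Zero between-subject
variance drives the ICC to its $\le 0$ boundary with an explicit flag; an
all-tied score vector gives AUC 0.5 and a degenerate-cutoff warning. All
simulator entry points are deterministic per seed, and a fixed cohort,
configuration and seed reproduce byte-identical JSON reports.

## Known limitations

* The device's internal algorithm (references describing it are not
  restated in the source study) may filter, window, or define the 90%
  return differently; agreement with this implementation on real SD-card
  recordings is untested.
* The single-exponential model ignores biphasic or overshooting recoveries;
  they surface only as low $R^2$.
* DeLong intervals and the proportional-bias $t$-test are asymptotic; at
  n = 30 they are indicative, not exact.
* The simulator's admission labels carry no relationship to covariates
  beyond the group-wise refill-time moments.
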