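# refillr

Quantifies **blood refill time (BRT)** — an objective, device-based analogue
of bedside capillary refill time — from fingertip photoplethysmography, and
provides the paired-method comparison statistics needed to evaluate it
against standardized visual CRT.

## The problem and who this is for

Capillary refill time (how long a blanched fingertip takes to regain its
colour) is a standard bedside perfusion check, but visual timing is
subjective. A single-wavelength (940 nm) transmission pulse-oximetry sensor
offers an objective alternative: compressing the fingertip squeezes
haemoglobin out of the optical path so transmitted intensity rises, and on
release the intensity relaxes back as blood refills the capillary bed. This
package is for researchers processing such compression-release recordings
and for methodologists running agreement/diagnostic-accuracy studies of
refill-time measurements.

## The model

The post-release recovery is fit by least squares as an exponential decay

```
I(t) = B + A * exp(-t / tau)
```

where `A` is the intensity elevation at release, `tau` the recovery time
constant, and `B` the recovered asymptote. BRT is the time for the fitted
curve to complete 90% of its drop:

```
BRT = tau * ln(10)
```

The fit is *separable*: for fixed `tau` the optimal `(A, B)` are closed
form, so `tau` is found by a log-grid scan plus Brent refinement over
[0.05, 60] s — no starting values, globally robust.

Around the core fit the package provides: compression-window detection,
baseline estimation, cardiac-pulsation smoothing, triplicate averaging, a
synthetic waveform/cohort simulator with known ground truth, Pearson
correlation, Bland–Altman limits of agreement with a proportional-bias
test, Shrout–Fleiss intraclass correlation with confidence intervals,
ROC/AUC with DeLong intervals, left-upper-corner optimal cutoffs, and 2×2
diagnostic metrics — plus `run_study()`, which strings the whole comparison
together.

## Worked example

```r
library(refillr)

# one trial: simulate a compression-release trace (true tau = 1.5 s,
# so true BRT = 1.5 * ln10 = 3.454 s) and measure it back
sim <- simulate_waveform(tau = 1.5, seed = 7)
m <- measure_brt(sim$trace)
print(m)
#> BRT measurement
#>   BRT = 3.279 s  (tau = 1.424 s, 90% return at tau*ln10)
#>   window: compression 5.000 -> release 10.000 s, baseline 501.0
#>   fit: A = 84.35, B = 504.03, R^2 = 0.9895, n = 908
```

The measured BRT (3.279 s) sits within 5% of the ground truth under the
default cardiac pulsation and noise; `coef(m)`, `predict(m)`,
`residuals(m)` and `plot(m)` inspect the fit like any model object.

```r
# a full method-comparison study on a simulated 30-subject cohort
rep <- run_study(simulate_cohort(seed = 42))
print(rep)
#> Refill-time method comparison (n = 30 subjects)
#>   admission rate: 53%
#>   CRT-BRT Pearson r = 0.748 (p = 1.98e-06)
#>   Bland-Altman bias (BRT - CRT) = 2.087 s, LoA [-3.04, 7.22]
#>   ICC single: CRT 0.872, BRT 0.954
#>   admission AUC: BRT 0.603, CRT 0.638; BRT cutoff 3.27 s
#>   at cutoff: sens 62.5%, spec 57.1%, PPV 62.5%, NPV 57.1%
```

The positive Bland–Altman bias says the device reads systematically longer
than visual CRT (with spread growing with magnitude — proportional bias,
built into the simulated cohort as in the clinical data); the ICCs
summarise triplicate repeatability; the AUCs measure how well each method's
subject mean predicts hospital admission, with the BRT cutoff chosen at the
ROC point nearest the ideal (0, 1) corner.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/refillr simulate-cohort --seed 1 --out cohort.csv
Rscript inst/cli/refillr compare --in cohort.csv --out report.json
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
triplicate waveform simulation and BRT measurement, then the full simulated
cohort comparison — and writes its JSON result file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/blood-refill-time.Rmd`) explains the
model and its assumptions, every tunable parameter with units and defaults,
what the simulator does and does not emulate, numerical edge-case handling,
and known limitations.
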