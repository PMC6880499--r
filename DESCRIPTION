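Package: refillr
Title: Blood Refill Time from Fingertip Photoplethysmography with
    Method-Comparison Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies blood refill time (BRT) from fingertip
    transmitted-light photoplethysmography traces recorded around a timed
    5-second compression: segments the compression/release window, estimates
    the pre-compression baseline, fits an exponential recovery
    I(t) = B + A*exp(-t/tau) by separable least squares, and reports the
    time to 90 percent intensity return (tau*ln 10). Includes a synthetic
    waveform and cohort simulator with known ground truth, paired-method
    agreement statistics (Pearson correlation, Bland-Altman limits of
    agreement with a proportional-bias test, Shrout-Fleiss intraclass
    correlation with confidence intervals), ROC/AUC analysis with a DeLong
    interval and left-upper-corner optimal cutoff, 2x2 diagnostic metrics,
    and a study pipeline for capillary-refill method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
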