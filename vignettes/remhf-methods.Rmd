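---
title: "Discriminating REM sleep from wakefulness with high-frequency EEG band power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating REM sleep from wakefulness with high-frequency EEG band power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remhf)
```

## The problem

Scoring rodent sleep conventionally needs two signals: the EEG to separate
NREM sleep (high-amplitude delta, 0.1–4 Hz) from the rest, and the EMG to
separate REM sleep from wakefulness, because the REM EEG is
theta-dominated and otherwise looks deceptively "awake". EMG electrodes are
an extra surgical and signal-quality burden, so an EEG-only route to the
REM/wake distinction is attractive. The observation `remhf` operationalizes
is that the *high-frequency* part of the epidural EEG (80–500 Hz, far above
the classical sleep bands) systematically separates the two states: power in
those bands is elevated during wakefulness and suppressed during REM sleep.

The package implements the complete analysis as a reusable pipeline:

1. a seeded synthetic polysomnography generator (because real recordings of
   this kind are distributed on request only, every stage must be testable
   without them);
2. semi-automated reference scoring from EMG RMS, delta and theta activity;
3. per-epoch spectral feature extraction over nine bands spanning
   0.1–500 Hz, with artifact excision, Grubbs outlier replacement and
   z-scoring;
4. a from-scratch kernel naive-Bayes classifier (with Gaussian NBC, QDA and
   k-NN comparators) for REM-vs-wake epoch classification;
5. the evaluation protocol: repeated shuffled 75/25 splits,
   accuracy/sensitivity/specificity, ROC/AUC, per-band false-negative-ratio
   ablation, hourly power/state correlations, and the nonparametric tests.

## The classifier

For feature vector $x = (x_1, \dots, x_9)$ (one band-average power per
band) and class $c \in \{\text{WAKE}, \text{REM}\}$, naive Bayes assumes
conditional independence:

$$ \log P(c \mid x) \;\propto\; \log \pi_c + \sum_{j} \log \hat f_{c,j}(x_j), $$

where $\hat f_{c,j}$ is a one-dimensional Gaussian kernel density estimate
over the training values of feature $j$ in class $c$:

$$ \hat f_{c,j}(x) = \frac{1}{n h}\sum_{i=1}^{n} \phi\!\left(\frac{x - x_i}{h}\right),
\qquad h = 0.9\,\min(\mathrm{SD}, \mathrm{IQR}/1.34)\, n^{-1/5}. $$

Numerical choices, all tested:

* accumulation in log space with log-sum-exp normalization, stable for
  feature magnitudes to at least $10^6$;
* per-feature log densities floored at $\log 10^{-300}$, so one far-out
  feature cannot single-handedly veto a class;
* bandwidths floored at $10^{-6}$ of the feature range for degenerate
  spreads;
* priors are empirical class frequencies by default. With REM at roughly 5%
  of a day against 47% wakefulness this matters: it is what drives the
  classifier to the majority class when features carry no signal, the
  mechanism behind the ablation analysis below. `priors = "uniform"` is
  available.

The kernel, bandwidth rule and prior handling are this package's declared
choices; they are standard defaults, not values inferred from any particular
toolbox.

QDA and k-NN are implemented from scratch as comparators (full-covariance
Gaussian discriminant with ridge repair for singular covariances; Euclidean
k-NN with fixed tie rules: vote ties go to the nearest neighbour, distance
ties to the lower training index). An SVM comparator is deliberately *not*
re-implemented and no SVM backend ships in this package's dependency set;
`method = "svm"` says so rather than silently substituting.

## Features

Each 4-s epoch is reduced to nine band-average powers over
0.1–4, 4–8, 8–13, 13–30, 30–80, 80–120, 120–200, 200–350 and 350–500 Hz.

* **PSD estimator.** A single-taper periodogram per epoch, mean removal
  only, 0.25-Hz resolution at the default 4 s × 1000 Hz. The simplest
  estimator consistent with features "from the raw signal"; it satisfies
  Parseval exactly, which the tests exploit as an oracle.
* **"Average power".** Band-integrated power divided by bandwidth
  (units µV²/Hz), so bands of very different widths are comparable. Whether
  the original analysis normalized by bandwidth is not documented;
  `band_power_mode = "integrated"` preserves the other reading. The
  classifier is insensitive to the choice (it is a per-band positive
  rescaling, and features are z-scored per band anyway).
* **Band edges.** Half-open intervals $[low, high)$; the nominal 0.1-Hz
  lower edge maps to the first non-DC bin (0.25 Hz), and the 500-Hz upper
  edge excludes the Nyquist bin.
* **Artifact excision.** Samples exceeding a manual threshold mark artifact
  peaks; each peak ±50 ms is replaced by linear interpolation between
  flanking clean samples, overlapping windows merged. The threshold is a
  per-recording manual choice in practice; `robust_artifact_threshold()`
  (6 × the MAD estimate of the SD) is the provided default. Epochs with
  more than 5% of samples excised are dropped — the recording-level "more
  than 5% movement artifacts" exclusion transliterated to epoch level.
* **Grubbs outlier replacement.** The two-sided Grubbs test applied
  iteratively per band across all epochs of a recording (one outlier removed
  per iteration while the test rejects at α = 0.05), flagged values replaced
  by linear interpolation between non-outlier neighbours. Scope and α are
  not documented in the source analysis; per-recording/per-band at 0.05 is
  this package's declared choice. A constant series is "no outliers", and a
  series where iteration would leave fewer than three points is an error.
* **z-scoring.** Per band, across the recording's epochs, sample-SD
  denominator — the step that makes features comparable across animals.

## The synthetic generator: what it emulates and what it does not

The generator is a stated world, not a tuning knob. Defaults encode a 23-h
mouse recording started at 09:00 (light onset) under a 12/12-h light/dark
cycle, 1000 Hz sampling, 4-s epochs, and an overall state budget of
47% wake / 48% NREM / 5% REM.

**Hypnogram.** A per-epoch Markov chain with geometric dwell times (means:
WAKE 60, NREM 40, REM 12 epochs) whose embedded jump chain is calibrated in
closed form so the stationary law matches the phase-specific target
fractions exactly. Circadian structure enters by modulating the targets:
WAKE is scaled up 30% in the dark phase and down in the light phase, REM the
reverse at 50% (a nocturnal animal). One honest constraint: no jump chain
can give a state more than half its jump-stationary mass (a state cannot
leave more often than the others combined arrive), so when phase-modulated
targets collide with the configured dwell means the generator lengthens the
offending state's bouts minimally. Bout lengths do vary with circadian phase
in real animals, so this is the right degree of freedom to bend.

**Signals.** Per epoch, stationary Gaussian noise synthesized in the
frequency domain with one-sided PSD

$$ S(f) = c^2 f^{-\beta}
   + \textstyle\sum_b g^2_{s,b}\,\mathbf 1[f \in b]
   + a_\delta^2(s)\,\mathbf 1[f \in 1\text{–}4]
   + a_\theta^2(s)\,\mathbf 1[f \in 6\text{–}9], $$

with $\beta = 1$ background, per-state band gains $g_{s,b}$, and delta/theta
narrowband components carrying the NREM-delta and REM-theta signatures.
FFT-mask synthesis gives exact band edges with no filter ringing, and
consecutive epochs are stitched with a 10-ms raised-cosine crossfade so
boundary steps do not leak broadband power. The high-band (80–500 Hz) gains
are ordered WAKE (1.0) > NREM (0.55) > REM (0.35): the sign structure the
pipeline exploits, with amplitudes chosen once so that the z-scored
high-band features separate WAKE from REM by roughly 2 SD of the pooled
epoch distribution. No quantitative spectral model of the real signals is
published; these defaults reproduce the *sign* structure of the reported
hourly correlations, not their magnitudes. EMG is white noise with per-state
RMS 8/2/1 µV (WAKE/NREM/REM — REM atonia). Movement artifacts are
raised-cosine transients (10 × SD, 20–100 ms) added to WAKE epochs with
probability 0.05, with ground-truth onset times returned for testing the
excision stage.

What the generator deliberately does **not** model: biophysical coupling,
real bout-length distributions (heavy-tailed in practice), electrode-site
differences beyond independent channel noise, state transitions inside an
epoch, volume-conducted muscle tone. A green end-to-end test therefore
establishes that the pipeline's machinery is correct and that it recovers
structure *of the kind assumed*, not that the published real-data
performance numbers are reproduced — those depend on request-only
recordings and are quoted only as context.

## Reference scoring

The semi-automated rules: WAKE when EMG RMS is at/above threshold; with
sub-threshold EMG, NREM when delta power is above threshold, REM when delta
is below and theta above threshold. Three declared choices where the rules
underdetermine behaviour:

* epochs with sub-threshold EMG, delta *and* theta match no rule and are
  assigned WAKE (REM demands positive theta evidence); they are counted and
  exposed as `rule_gap`;
* runs shorter than 3 epochs are micro-states, not genuine state changes:
  smoothing absorbs the shortest run first into the preceding surviving
  state (a leading run takes the following state), is idempotent, and
  leaves no short runs;
* the scoring theta band defaults to 4–8 Hz to match the feature table
  (rodent theta is often quoted as 6–9 Hz; the edges are configurable).

`calibrate_thresholds()` — midpoints of class-conditional metric means on
labelled calibration data — is a convenience stand-in for the interactive
manual threshold choice and is flagged as such.

## Evaluation protocol

Only WAKE and REM epochs enter the binary task; REM is the positive class.
The data are split 75/25 at the epoch level without stratification (the
plain reading of a random split of data points; a `stratified` flag exists),
re-shuffled `n_shuffles` times (1000 in the full protocol; desk-scale runs
use 50, by which point the standard error of the means is well under half a
percentage point), and means ± SD reported. Splits that lack a class on
either side are redrawn and counted. Sensitivity + FNR = 100 exactly, by
construction. ROC curves sweep the posterior threshold; AUC uses the
trapezoid rule and equals pair concordance, which the tests verify. The
per-band ablation feeds the classifier one band at a time: a band that does
not separate the classes collapses the (empirical-prior) classifier to the
majority class, pushing REM FNR toward 100% — the reason sensitivity and
specificity, not accuracy, are the headline metrics under a 5% positive
class. Pearson correlations between hourly mean z-scored band power and
hourly state percentages use the product-moment formula, Fisher-z 95%
intervals and t-distribution p-values, gated by a Shapiro–Wilk normality
screen that warns rather than stops. Mann–Whitney U and the one-sample
Wilcoxon signed-rank test (hypothetical median 100, for the FNR analysis)
use exact enumeration at small n and tie-corrected normal approximations
otherwise, with two-tailed p at α = 0.05 and no multiple-testing
correction, matching the source protocol.

Two aggregation subtleties are exposed rather than reconciled: per-recording
evaluation (the per-animal dots of the original ROC figure) is obtained by
running the protocol per recording, while pooled evaluation runs it on the
concatenated epochs; both paths are available through the same API.

## I/O and reproducibility

Signals travel as EDF (16-bit, µV, 1-s records — the lingua franca of sleep
labs; a float32 + JSON-header fallback exists for lossless tests),
hypnograms and feature tables as CSV, models and reports as JSON,
configuration as JSON. Every stochastic stage derives its RNG stream from
the configured seed: identical configuration reproduces every report
byte-for-byte, which the test suite asserts.

## Known limitations

* The 30–80 Hz band straddles the 50-Hz mains notch of the original
  hardware; like the source analysis, no compensation is applied (and the
  simulator's `notch_50hz` flag is off by default).
* The generator's spectral gains are free parameters with the right signs,
  not fitted magnitudes; absolute performance numbers on synthetic data are
  not comparable to real-data numbers.
* Exact Mann–Whitney enumeration is limited to 10 per group (and 15 for the
  signed-rank test) before switching to the normal approximation.
* Per-cortex analyses run by passing a different `channel`, but no reference
  values exist for synthetic data.
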