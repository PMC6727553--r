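---
title: "Rule-based five-stage sleep scoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based five-stage sleep scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnotree)
```

## The scoring problem

Rodent sleep studies classify every fixed-length window (here a 10-s
*epoch*) of an EEG+EMG recording into a vigilance stage. somnotree
implements a five-stage scheme — wake (`W`), light NREM (`N1`), deep NREM
(`N2`), transition sleep (`TS`), and REM (`R`) — with a collapse to the
classical three-stage scheme (`W`/`N`/`R`). The stages have characteristic
electrophysiological signatures:

* **Wake** — low-amplitude theta (6–9 Hz) over a broadband, desynchronized
  background, with large EMG tone.
* **NREM1** — sleep spindles (10.5–15 Hz) and/or moderate delta (0.5–5 Hz)
  occupying less than half the epoch; reduced EMG.
* **NREM2** — high-amplitude delta occupying more than half the epoch; low
  EMG.
* **TS** — theta intermixed with short (1–3 s) high-amplitude spindles; low
  EMG.
* **REM** — regular theta with essentially absent EMG tone.

The classifier is a fixed rule system, not a trained model: a two-part
decision tree with seven testing points over spectral features, preceded by
a per-recording calibration that removes between-subject amplitude
differences. `score_recording()` runs the whole pipeline and returns a
classed object with the hypnogram and a full audit trail.

## Features

Each 10-s epoch is divided into five non-overlapping 2-s segments. Per
segment, ten features are computed:

* **Six band powers (dB)** on the 0.5-Hz grid of a 2-s rectangular-window
  periodogram: `lo` [0, 0.5), `delta` [0.5, 5), `theta` [6, 9), `alpha`
  [10.5, 15), `beta` [22, 30), `gamma` [35, 45) Hz. The band power is
  $10\log_{10}$ of the *mean* bin power across the band (a floor of
  $10^{-12}\,\mu V^2$ inside the logarithm keeps silent segments finite at
  −120 dB). We deliberately take the dB of the mean power rather than the
  mean of per-bin dB values: the latter is a geometric mean dominated by
  the broadband noise floor (weight $(k-1)/k$ for a $k$-bin band), which
  would make every band feature track background level instead of the
  band's oscillation and invert the stage ordering the indexes rely on.
* **Three raw power ratios**: band power summed over `lo`, `delta`, or
  `alpha` bins divided by total 0–30 Hz power. These stay on their natural
  $[0,1]$ scale because the tree's thresholds (0.5, 0.3) carry "fraction of
  the epoch's power" semantics.
* **EMG energy**: mean absolute amplitude of the EMG after a zero-phase
  4th-order Butterworth band-pass at 10–100 Hz applied to the whole channel
  (forward–backward filtering preserves the EEG/EMG time alignment).

The periodogram is not demeaned and its DC bin is kept: the `lo` band *is*
the DC bin, which carries the baseline shifts that movement artifacts
produce. No resampling is performed anywhere; EEG and EMG features for
segment $k$ cover the same time window at each channel's native rate.

## Per-recording calibration

Each of the ten features is normalized per recording by extreme-decile
scaling: the mean of the 10% smallest values maps to 0, the mean of the 10%
largest to 1, everything clips into $[0,1]$ (`decile_normalize()`). The
decile count is $\lceil 0.1 n \rceil$, at least 1. A constant feature maps
to 0.5 everywhere, keeping downstream denominators defined without biasing
any stage. Bounds are computed once over all segments of the recording
(the offline, full-session setting); `write_bounds()`/`read_bounds()` allow
re-scoring with a stored calibration.

Two calibration utilities support threshold engineering on new data: the
distribution distance
$DD(A,B) = 1 - (\sigma_A + \sigma_B) / (2|\bar A - \bar B|)$ when
$\sigma_A + \sigma_B \le 2|\bar A - \bar B|$ and 0 otherwise (a
separability score for a feature between two stages, defined as 0 in the
degenerate equal-point case), and `feature_threshold()`, the midpoint
between the upper decile pulled down by half its spread and the lower
decile pushed up by half its spread. The shipped tree uses the fixed
published constants; no re-learning is performed.

## Stage indexes

From the normalized features (EMG, $\delta, \theta, \alpha, \beta, \gamma$,
$lo$), four primary indexes target one condition each:

$$\mathrm{Index}_W = \frac{EMG \cdot \gamma}{\delta}, \quad
\mathrm{Index}_N = \frac{\delta \cdot \alpha}{\gamma^2}, \quad
\mathrm{Index}_R = \frac{\theta^3}{\delta \cdot \alpha \cdot EMG}, \quad
\mathrm{Index}_A = \frac{(2 \cdot lo + \beta)\,\gamma}{\delta + \theta +
\alpha + \beta + \gamma}$$

and four secondary indexes serve the second tree part:
$\mathrm{Index}_1 = EMG\cdot\gamma/\delta$ (identical to
$\mathrm{Index}_W$), $\mathrm{Index}_2 = \alpha\cdot\delta/\theta$,
$\mathrm{Index}_3 = \theta\cdot\gamma/\delta$,
$\mathrm{Index}_4 = \delta/\theta$.

Two numerical choices matter here:

* **Denominator floor 0.01.** Extreme-decile clipping maps roughly a tenth
  of all segments to exactly zero per feature *by construction*, so
  denominators must be floored. The floor is 1% of the normalized range —
  the resolution below which a 2-s band-power estimate carries no usable
  information. A much smaller floor makes a single noise-clipped segment
  produce index values many orders of magnitude above everything else,
  which then dominates every epoch average; at 0.01, genuinely extreme
  signatures (REM atonia driving $\mathrm{Index}_R$) still dominate by two
  to three orders of magnitude, while noise-driven blow-ups stay bounded.
  Numerators are never floored.
* **Epoch indexes from epoch-averaged features.** The first tree part needs
  one index value per epoch, computed from the average of the five 2-s
  normalized feature vectors (`epoch_indexes()`): features are averaged
  first, then the ratios are formed. Averaging per-segment index values
  instead is unstable — one clipped segment's floored ratio can hijack the
  epoch mean. Per-segment indexes (`compute_indexes()`) remain the currency
  of the second tree part, whose testing points count segments, and
  `aggregate_epoch()` provides plain index averaging for audit purposes.

The indexes are used on their natural scale; no second decile
normalization is applied to them. With clipping producing exact zeros,
re-normalizing a floored ratio series degenerates into a near-binary
indicator and destroys the $\mathrm{Index}_1$-vs-$\mathrm{Index}_2$ and
$\mathrm{Index}_3$-vs-$\mathrm{Index}_4$ comparisons; the part-1 arg-max
needs no common scale to be meaningful.

## The decision tree

Part 1 routes each epoch into a condition; part 2 refines it into a stage.
All comparisons are strict (`>`); a value exactly at a threshold falls to
the else branch. All constants live in `tree_config()`.

1. **Artifact** (testing point 1): if
   $\mathrm{Index}_A / (\mathrm{Index}_N + \mathrm{Index}_R +
   \mathrm{Index}_A) > 0.9$, the epoch is a movement artifact. It is scored
   `W` in the hypnogram but keeps its artifact flag — the information is
   preserved rather than discarded.
2. **Condition**: arg-max of $\mathrm{Index}_W, \mathrm{Index}_N,
   \mathrm{Index}_R$; exact ties break in the order W > N > R (wake is the
   default for ambiguous epochs).
3. **W branch** (testing points 2–3): `W` if the raw low-band ratio exceeds
   0.5 in ≥ 1 segment (movement-contaminated wake); else `W` if
   $\mathrm{Index}_1 > \mathrm{Index}_2$ in *all five* segments; else `N1`.
4. **N branch** (testing points 4–6, evaluated in order): `W` if the
   low-band ratio exceeds 0.5 in ≥ 2 segments; else `TS` if
   $\mathrm{Index}_3 > \mathrm{Index}_4$ in ≥ 3 segments; else `N2` if the
   raw delta ratio exceeds 0.5 in ≥ 3 segments (delta occupying more than
   half the epoch); else `N1`.
5. **R branch** (testing point 7): `TS` if the raw alpha ratio exceeds 0.3
   in ≥ 1 segment (spindles embedded in theta); else `R`.

The band-power-ratio tests consume the *raw* ratios, not their normalized
forms: the 0.5/0.3 constants encode absolute spectral composition
("delta > 50% of the epoch"), which per-recording normalization would
destroy. The normalized ratio features are still produced for export and
API uniformity.

## Agreement statistics

`confusion()`, `overall_agreement()`, `cohens_kappa()`, `stage_metrics()`,
`kappa_band()`, and `consensus_epochs()` implement the validation
machinery: expert-consensus filtering, the confusion matrix, overall
agreement (trace/total), Cohen's $\kappa$ with the Landis–Koch
interpretation bands, and one-vs-rest sensitivity/specificity/predictive
values. `stage_metrics()` takes an explicit `reference_axis`: `"rows"` is
the conventional reading (rows = expert reference) and the documented
default; `"columns"` reproduces the convention of the published validation
tables shipped as fixtures (`validation_confusion()`), whose printed
sensitivities are computed against the automatic-staging margin.
Statistics with zero denominators are reported as `NA`, never as 0 or 100.

## The synthetic generator

`generate_hypnogram()` samples a ground-truth hypnogram from a five-state
Markov chain (default: physiological progression with self-transition
0.8); `generate_recording()` renders it as EEG (200 Hz) + EMG (500 Hz).
Each stage recipe is white Gaussian broadband noise plus the
stage-defining oscillations:

| stage | oscillations | EEG noise sd | EMG noise sd |
|---|---|---|---|
| W  | 7-Hz theta, 5 µV, whole epoch | 15 µV | 80 µV |
| N1 | 2-Hz delta 60 µV in 2/5 segments; two 1-s 12-Hz spindles 40 µV | 5 µV | 25 µV |
| N2 | 2-Hz delta 120 µV in 4/5 segments | 4 µV | 15 µV |
| TS | 7-Hz theta 40 µV; three 1.5-s 12-Hz spindles 60 µV | 5 µV | 10 µV |
| R  | 7-Hz theta 40 µV | 8 µV | 3 µV |

Three design points deserve explanation:

* **EEG noise levels** encode the physiological ordering of high-frequency
  background (activated states W and R above NREM). In a white-noise
  generator the noise floor is the *only* carrier of beta/gamma-band
  information, which $\mathrm{Index}_W$ and $\mathrm{Index}_N$ both
  consume.
* **Wake theta is genuinely low-amplitude** (5 µV against a 15-µV
  broadband background — still a clear 7-Hz spectral peak). Wake must not
  approach REM's theta after normalization: $\mathrm{Index}_R$ cubes the
  normalized theta, so a wake theta at, say, three quarters of REM's
  normalized value would rival $\mathrm{Index}_W$ on wake epochs.
* **Raised-cosine 0.25-s ramps** on every oscillation onset/offset. A
  hard-switched sinusoid splatters power across the whole spectrum
  (spectral leakage of the rectangular gate), inflating theta estimates in
  NREM segments and corrupting the band features the rules read.

What the generator does *not* emulate: 1/f background spectra,
non-Gaussian EMG bursts, electrode drift, inter-individual amplitude
differences, or the real joint distribution of features within a stage.
Passing recovery tests therefore demonstrates the internal consistency of
the pipeline — that the rules recover stages whose defining signatures are
present — not field performance on animal recordings.

## Problem sizes and verification

The test-suite and acceptance script use desk-scale problem sizes chosen
to keep the full run in the minutes range: 600-epoch (100-min) synthetic
recordings for ground-truth recovery, 10,000 randomized feature epochs for
the rule-transcription equivalence check, 10,000-epoch hypnograms for the
Markov stationarity check, and the published 168,656-epoch confusion
matrices for the agreement arithmetic. Every derived formula example is
checked against independent hand or brute-force evaluation at
$10^{-9}$ relative tolerance; the scorer itself is validated by (a) exact
agreement with an independent straight-line transcription of the seven
rules, (b) ground-truth recovery on clean synthetic recordings, and (c)
the structural inequality that collapsing to three stages can never lower
agreement.

## Known limitations

* The tree's node wiring follows the published textual rule description;
  thresholds are fixed constants, and no re-learning from labeled data is
  provided (the calibration utilities support it externally).
* Band gaps (5–6, 9–10.5, 15–22, 30–35 Hz) are excluded by design, so
  oscillations falling there are invisible to the features.
* The EDF writer emits a minimal two-channel continuous-recording subset
  of the format (16-bit, 1-s records, integer rates); EDF+ annotations are
  not supported.
* Scoring is offline per recording: the default calibration needs the full
  session's feature distribution. For streaming use, apply stored bounds
  via `score_recording(rec, bounds = read_bounds(...))`.

## A worked example

```{r example}
hyp <- generate_hypnogram(120, seed = 7)
rec <- generate_recording(hyp, seed = 8)
fit <- score_recording(rec)
summary(fit)
mean(as.character(fit$hypnogram) == as.character(hyp))
```
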