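---
title: "Windowed Markov-chain analysis of RR-interval states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed Markov-chain analysis of RR-interval states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsamarkov)
```

## The model

Heart rate variability is carried by the sequence of RR intervals, the
durations (ms) between consecutive R peaks of the EKG. `rsamarkov` reduces
each interval to one of two states — Normal (`N`) when it lies inside a
closed reference band α = [lower, upper] ms, Arrhythmic (`A`) otherwise —
and treats the resulting label sequence X₀, X₁, X₂, … as a realisation of
a first-order, two-state Markov chain. The object of inference is the
row-stochastic transition matrix

$$P = \begin{pmatrix} P_{AA} & P_{AN} \\ P_{NA} & P_{NN} \end{pmatrix},
\qquad P_{AA}+P_{AN} = 1,\; P_{NA}+P_{NN} = 1.$$

Rather than one matrix per record, the analysis estimates a matrix in
every position of a moving window of $W$ intervals, by counting the
$W - 1$ adjacent ordered state pairs inside the window and dividing each
count by the number of transitions leaving its origin state. The
window-level probabilities, pooled over all windows of all records of a
subject group, are the samples on which groups are compared (two-sided
Mann–Whitney U per transition type).

Assumptions worth keeping in view: first-order dependence (the next state
depends only on the current one), homogeneity within a window, and — for
the group test — exchangeability of pooled window values between groups.
The last one is the weakest link; see *Limitations*.

## Parameters

* **Band α (ms).** `alpha_band(lower, upper)`; presets
  `default_band("arachnophobia")` = [800, 1000] and
  `default_band("blood_pressure")` = [900, 1100], both centred near a
  resting mean RR of ≈ 900 ms. Both bounds are **inclusive**: the band is
  a closed interval, and values are compared at full float precision. `A`
  covers deviation on either side; bradycardic and tachycardic excursions
  are not distinguished.
* **Window size `window_size`** (RR intervals, default 10). At a ≈ 900 ms
  mean RR a 10-beat window spans roughly 6–12 s of recording. Smaller
  windows make the per-window ratio estimates coarser (denominators of at
  most `window_size` − 1); larger windows smooth over transient episodes.
* **Step `step`** (intervals, default 1). How far the window advances.
  The default gives maximally overlapping windows — the natural reading
  of a "moving window", and the configuration under which pooled sample
  counts reach the thousands even for short records. It is also what
  makes consecutive window values strongly dependent (see *Limitations*).
  Setting `step = window_size` gives non-overlapping, nearly independent
  windows.
* **Detector settings** `refractory_ms` (default 250, a 240 bpm ceiling)
  and `threshold_factor` (default 0.5, fraction of the rolling energy
  maximum). The automatic detector is a stand-in for manual beat
  annotation, which remains the careful-practice reference; exact
  agreement with a human annotator is nowhere assumed.

## Numerical choices

* **Undefined rows.** A window in which state *i* never occurs before the
  last position has no outgoing *i*-transitions; its row is `NA` and is
  excluded from the pooled samples. Imputing 0 or 0.5 would fabricate
  probabilities and silently break row conservation.
* **Conservation.** Each defined row sums to 1 exactly (integer count
  divided by the row total); the test suite asserts a 1e-12 bound across
  a randomized suite of thousands of windows.
* **Mann–Whitney.** Midranks for ties. Exact mode enumerates all
  assignments of the pooled ranks to the first sample and remains valid
  under ties; it is selected automatically when `min(n_x, n_y) ≤ 8` *and*
  `choose(n_x + n_y, n_x) ≤ 2e5` (without the second guard the rule is
  unbounded in the larger sample). Otherwise the normal approximation is
  used with the tie-corrected variance and a 0.5 continuity correction.
  Ties dominate the pooled samples — window probabilities concentrate on
  a small grid of ratios, mostly 0 and 1 — so explicit tie handling is
  essential, and it is also why `stats::wilcox.test` (which refuses exact
  computation under ties) serves only as a cross-check in the tests.
  Two-sided p-values throughout; the reported SD is the sample SD
  (denominator n − 1); no multiple-testing correction across the four
  transitions, which are reported as raw rows.
* **Complement structure.** Within a window, P(A→N) = 1 − P(A→A) whenever
  defined. Pooled A→N and A→A samples are therefore pointwise
  complements: group means sum to 1, SDs coincide, and the rank test
  returns the same p-value for both rows (a rank test is invariant under
  strictly decreasing transforms). The four-row report thus contains two
  independent comparisons, printed in four rows for readability.
* **Peak indices** are 0-based sample offsets, so time = index / fs with
  no off-by-one; RR derivation uses only index differences.
* **Units** are fixed to milliseconds. Second-scale values (< 10 ms)
  trigger a loud warning rather than silent conversion.
* **File dialect.** RR/IBI files are one value per line; blank lines and
  `#` comments are ignored; commas and stray whitespace are tolerated.
  The one-value-per-line layout is an assumption about deposited `.txt`
  IBI files, made explicit here.

## The synthetic generators

`simulate_markov_rr()` draws a hidden two-state chain (started from its
stationary law unless forced) and emits uniform in-band durations in
state `N` and uniform out-of-band durations — in a 200 ms strip above,
below, or on both sides of the band — in state `A`; optional Gaussian
jitter is clipped so emissions stay on the correct side of the band
edges. Classification therefore recovers the hidden states *exactly*,
which is the property that lets the estimator, the window machinery and
the group test be checked against ground truth. The 200 ms strip width is
a simplicity choice: it keeps arrhythmic emissions physiologically
plausible (within ±200 ms of the band) and verifiable, where no
distributional form for out-of-band intervals is established.

`simulate_rsa_rr()` produces a respiratory-style fixture: RR length
follows a sinusoid in elapsed time (defaults 900 ms mean, 80 ms
amplitude, 0.25 Hz — 15 breaths/min) plus Gaussian noise, hard-clipped at
1 ms. It is a signal shape, not a cardiac model: no baroreflex loop, no
integral pulse frequency modulation, no respiratory–cardiac phase
coupling. `simulate_ekg_pulsetrain()` places unit triangular pulses at
cumulative beat times rounded to the sample grid, returning the planted
peak indices as the detector's oracle.

What passing tests on these fixtures shows: the estimator, pooling and
test machinery are correct, and the EKG→peak→RR path is exact on clean
signals. What they do not show: robustness to ectopic beats, movement
artefacts, missed or spurious detections, and non-stationary real
recordings — all of which manual annotation and visual inspection address
in practice.

## Design choices where the design was open

* **Step = 1** as the default. Overlap maximises the number of windows
  and is consistent with pooled sample sizes large enough to produce
  p-values in the 1e-6 range from a handful of subjects; it is kept
  configurable.
* **Pooling unit.** Window-level values from all records of a group are
  pooled into one sample per transition. Pooled SDs of ≈ 0.37–0.48 around
  means of 0.2–0.8 are only consistent with samples dominated by 0/1
  window values, not with a few per-record means — so the pooled reading
  is adopted. Concatenating records before windowing would instead count
  spurious cross-record "transitions" and is not done.
* **Exact vs approximate U test** is chosen by sample size (`auto`),
  since pooled samples are far beyond exact enumeration anyway.

## Problem sizes used in the checks

The suite works at sizes chosen to make sampling error small relative to
the asserted tolerances while keeping a laptop run comfortable: a
100,000-interval record for parameter recovery (whole-sequence estimates
within ±0.01 of the generating matrix; pooled window means within ±0.02
of an independently coded Monte-Carlo oracle at a different seed),
1,000-window randomized suites for conservation and oracle equivalence,
full enumeration for all Mann–Whitney splits up to 12 observations, and
200 replicates per arm for the false-positive and power checks on
5-record × 300-interval groups.

## Limitations

* **Autocorrelation of overlapping windows.** With `step = 1`,
  consecutive windows share all but one interval, so pooled samples are
  strongly autocorrelated, while the Mann–Whitney test treats them as
  independent. The test is therefore anticonservative for record-level
  null hypotheses: in the suite's same-process check (two groups of five
  300-interval records from an identical generating matrix), far more
  than 1% of replicates fall below p = 0.01 — roughly a third do — whereas
  the identical test on independent samples, or on non-overlapping
  windows (`step = window_size`), keeps its nominal level (both are also
  measured in the suite). The pooled procedure is reproduced as the
  method of record and this caveat documented rather than silently
  "fixed"; p-values from overlapping-window pooling should be read as
  descriptive indices of separation, not calibrated error rates. A
  cluster-robust or record-level analysis is the principled alternative
  and is deliberately out of scope here.
* **Two states only.** The band classification collapses all deviation
  into one state; no multi-band or adaptive, per-subject band estimation
  is provided.
* **First-order chain.** Higher-order dependence, continuous-time
  modelling, and spectral/stationary analysis of the estimated matrices
  are out of scope.
* **Detector.** The automatic R-peak detector is validated on synthetic
  pulse trains, not on annotated clinical EKG; for publication-grade HRV,
  manual review of detected beats remains advisable.
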