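---
title: "Measuring and coupling ERP latencies with dynamic time warping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and coupling ERP latencies with dynamic time warping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpwarp)
```

## The problem

Event-related potentials (ERPs) are stimulus-locked averages of EEG epochs.
Classical latency measures for ERP components — peak latency, fractional
peak, fractional area — depend on single points of the waveform and are
fragile under noise. `erpwarp` instead measures latency differences with
dynamic time warping (DTW), which aligns two whole waveforms and summarizes
the alignment geometry, and embeds that measure in two resampling schemes:
a paired sign-flip permutation test for "is component X later in condition B
than in condition A?", and a shared-sample participant bootstrap for "do the
latencies of components X and Y covary across participants?". The motivating
application is the coupling between the N2pc (a lateralized negativity
indexing the deployment of visual attention, analyzed at 150–400 ms) and the
P3 (a centro-parietal positivity associated with working-memory encoding and
conscious access, 250–800 ms), but every function operates on generic
participant × time matrices.

## The DTW latency measure

Given a reference waveform $r$ (by convention on the y-axis) and a query $q$
(x-axis), both windowed to the component's interval of interest and z-scored,
DTW builds the full local-cost matrix $c(i, j) = |q_i - r_j|$ and finds the
monotone path from $(1, 1)$ to $(n_x, n_y)$ with minimal cumulative cost
under the symmetric step set $\{(1,0), (0,1), (1,1)\}$, with no slope or
window constraint. Two derived statistics matter:

* **DTW area** $A = \sum_k (x_k - y_k)$ — the signed sum of horizontal
  distances between the path and the main diagonal, in sample units. $A > 0$
  means the path lies below the diagonal: the reference unfolds earlier than
  the query. $A = 0$ exactly when the series are identical. All statistical
  inference uses the area.
* **Latency** $\ell = \mathrm{median}_k(x_k - y_k) / (f_s / 1000)$ ms — the
  median of the horizontal distance distribution converted by the sampling
  rate. The latency is reported descriptively; it is deliberately not the
  test statistic.

z-scoring (sample SD, divisor $n-1$) is applied after window extraction so
that the path reflects contour differences rather than gross amplitude
differences; amplitude-confounded alignment would otherwise masquerade as a
latency effect. Windows are inclusive at both ends and window endpoints map
to samples by rounding $(t - t_0) f_s / 1000$.

Two open choices had to be fixed:

* **Area definition.** "The area between the warping path and the diagonal"
  admits a geometric polygon reading and a horizontal-distance-sum reading.
  We use the signed sum of horizontal distances over path points, which
  makes the area and the distance distribution internally consistent (the
  area is exactly the sum of the distribution) and keeps the sign
  interpretation trivial.
* **Tie-breaking.** When multiple predecessors of a cell tie in accumulated
  cost, backtracking prefers the diagonal move, then the vertical
  (reference-axis) move. Any fixed policy gives a valid minimal path; fixing
  one makes runs bit-reproducible. The cumulative distance is of course
  tie-free, and the test suite verifies it against exhaustive enumeration of
  all monotone paths for short series.

Known behavior inherited from the method: DTW systematically
*underestimates* injected latency shifts (by roughly 10–25% in our synthetic
checks, growing with noise), because the path can absorb part of a shift in
the flat flanks of a component. The shift-recovery tests therefore assert
recovery within ±25%, not exactness, and the noise sweep below quantifies
the degradation.

## Permutation test

For paired conditions (each of $n$ participants contributes one ERP per
condition) the null hypothesis of exchangeable conditions is simulated by
flipping each participant's pair with probability ½ — an independent fair
coin per participant, not a fixed-size subset — then recomputing both grand
averages, windowing, z-scoring, aligning, and recording the DTW area.
With 10,000 iterations (the default), the two-tailed p-value is the
proportion of absolute null areas at least as large as the absolute observed
area. The non-strict comparison ($\geq$) is the default because it is the
conservative convention and returns $p = 1$ (not 0/0 artifacts) in the fully
degenerate identical-conditions case; the strict variant is available via
`strict = TRUE`. Condition A is always the DTW reference, so area signs are
comparable across analyses.

## Shared-sample bootstrap coupling

To test whether two components' latencies covary across participants, each
bootstrap repetition draws **one** sample of participants with replacement
(of size $n$, the observed group size — not a free parameter) and reuses it
for both components. Per component, participant waveforms are windowed and
z-scored *at the participant level* before averaging; the bootstrap grand
average is aligned against the true observed grand average (the reference),
giving one signed area per component per repetition. Re-using the sample is
what makes the two areas of a repetition a pair; shuffling one marginal
destroys the correlation, which the suite asserts. After all repetitions the
two area distributions are z-scored and correlated (Pearson and Spearman —
the latter because the marginals are visibly heteroskedastic in real data);
z-scoring is cosmetic for Pearson (linear invariance, asserted numerically)
but makes scatterplots comparable. Marginal variance, skewness (biased
moment ratio $g_1$) and excess kurtosis ($g_2$) are computed on the raw
areas, before z-scoring.

Pairs in which either area lies beyond ±5 SD of its own marginal can be
removed with `exclude_outlier_pairs()`; the partner value from the same
repetition is always removed too, preserving pairing. Correlations between
conditions are compared with Fisher's Z transformation,
$v = 1/(n-3)$ per correlation for Pearson and the adjusted $1.06/(n-3)$ for
Spearman.

A caution that carries over from the method's origins: with thousands of
bootstrap repetitions the degrees of freedom are set by the analyst, so
p-values attached to these correlations are close to meaningless; interpret
the correlation coefficients (and differences between them) as effect sizes.

## Noise simulation

`noise_sweep()` answers "does a lower signal-to-noise ratio bias the latency
estimate?": a known delay (default 50 ms, zero-padded at the front) is
injected into a base waveform; EEG-spectrum noise scaled by $\lambda \in
[0, 0.95]$ is added to the shifted copy; both series are windowed
(150–400 ms default) and z-scored; DTW runs with the unshifted base as
reference; the latency estimate and the noisy series' SNR — RMS of
200–400 ms divided by RMS of −50–100 ms — are averaged over repetitions per
level. At $\lambda = 0$ the procedure is deterministic, and the zero-padded
head slightly distorts the z-scoring, which is why the level-0 estimate can
sit marginally below its low-noise neighbors. Because published summaries of
this analysis are ambiguous between "the estimate was X ms" and "the
estimate was short by X ms", the sweep reports `mean_latency_ms` and
`mean_underestimation_ms` side by side.

The noise generator uses the inverse-spectrum method: each FFT bin up to the
profile's range gets the target amplitude and an independent uniform phase;
the inverse transform is standardized and scaled by $\lambda$, so the output
SD equals $\lambda$ exactly. The default profile — a $1/f^{0.7}$ amplitude
decay over 1–45 Hz with a Gaussian alpha peak at 10 Hz (width 2 Hz) — ships
as an editable table from `eeg_spectrum()`, since the canonical "human EEG
spectrum" recipe is not fully specified anywhere; only the profile's shape
matters after standardization. The suite checks that the averaged
periodogram of generated noise correlates > 0.95 with the profile.

## Synthetic ERP generator

`generate_erp()` produces the statistical structure the inference tools
assume, with known ground truth: per participant, a component-1 latency from
$N(0, \sigma_\ell)$, a component-2 latency $a + b \cdot \ell_1 +
\varepsilon$, Gaussian-bump templates (a gamma-shaped asymmetric variant is
available to mimic the P3's skew) delayed by those latencies, independent
EEG-spectrum noise per epoch, and a "late" condition with both components
delayed by a fixed condition shift. Defaults emulate the study conditions
the package targets: 23 participants, 500 Hz, a −200–1000 ms epoch, an early
negative bump (275 ms center, 40 ms SD, amplitude 1) and a late broad
positive bump (500 ms, 90 ms, amplitude 2), 20 ms latency jitter SD,
unit-slope coupling with 10 ms residual SD, a 20 ms condition shift (the
order of magnitude reported for attention-sensitive components), and noise
$\lambda = 0.1$ — a high-SNR regime relative to the unit template amplitude.
The sampling rate is a package choice (ERP datasets commonly use 250–1000
Hz); all conversions read `fs` from the data, never assume it. Latency draws
that would push a bump outside the epoch are rejected and resampled, with
the retry count reported.

What the generator does *not* emulate: overlapping components, trial-level
variability (participant waveforms are noisy templates, not trial averages),
spatial topographies, and autocorrelated participant-specific noise spectra.
Passing the recovery tests therefore shows the machinery is correct and
calibrated under the assumed structure, not that real EEG meets that
structure.

## Numerical and design choices

* DTW is implemented in C++ (full $O(n_x n_y)$ matrix, no approximation);
  the brute-force enumeration oracle in the tests is the independent check.
* All stochastic functions accept a `seed` and consume R's RNG in a fixed
  documented order (latency draws before noise draws; one index sample per
  bootstrap repetition), so runs are bit-reproducible.
* Degenerate inputs fail loudly (constant series cannot be z-scored; empty
  distance distributions, windows outside the span and mismatched sampling
  rates are contract errors), except inside the bootstrap, where a constant
  resampled grand average is skipped and counted rather than aborting a
  10,000-repetition run.
* The zero-phase low-pass (`lowpass()`, default for slow components:
  25 Hz) is a 4th-order Butterworth applied forward and backward with
  odd-reflection edge padding, giving unit DC gain without startup
  transients.
* Test and example problem sizes are deliberately desk-scale: windows at
  250 Hz, hundreds to thousands of resampling iterations, 2,000 sweep
  repetitions per level. The statistical procedures are identical at
  production sizes (10,000 iterations, 25,000 repetitions); only means get
  tighter.

## Worked example

```{r example, eval = FALSE}
syn <- generate_erp(synth_spec(condition_shift_ms = 20), seed = 1)

perm <- permutation_test(syn$comp1$early, syn$comp1$late,
                         window = c(150, 400), n_perm = 2000, seed = 2)
perm

cp <- bootstrap_coupling(syn$comp1$early, syn$comp2$early,
                         window1 = c(150, 400), window2 = c(250, 800),
                         n_boot = 2000, seed = 3)
cp
exclude_outlier_pairs(cp, k_sd = 5)
```

## Limitations

* Inference is at the participant level; nothing here supports trial-level
  claims about component coupling.
* The latency estimate is biased toward zero; compare latencies measured
  under comparable SNR, and use the noise sweep to gauge the bias for your
  SNR regime.
* The bootstrap correlation of one dataset reflects that sample's accidental
  coupling (SD $\approx 1/\sqrt{n}$ across datasets even when the true
  coupling is zero); a single moderate correlation at $n = 23$ is weak
  evidence on its own.
* Single-channel waveforms only: channel selection, lateralized differences
  (`contra_ipsi_difference()`) and filtering are provided, but everything
  upstream (epoching, artifact rejection) is the user's concern.
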