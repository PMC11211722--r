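# erpwarp

Latency analysis for event-related potentials (ERPs) based on dynamic time
warping (DTW), for EEG researchers who want to ask two questions without
relying on fragile single-point latency measures:

1. **Is a component later in one condition than another?** (e.g. is the
   N2pc delayed on distractor-intrusion trials relative to correct trials?)
2. **Are the latencies of two components temporally coupled across
   participants?** (e.g. do the N2pc and the P3 shift together?)

## The method

Two waveforms — a reference $r$ (y-axis) and a query $q$ (x-axis), windowed
to the component's interval and z-scored — are aligned by DTW: the monotone
path through the cost matrix $c(i,j) = |q_i - r_j|$ with minimal cumulative
cost, using steps $\{(1,0),(0,1),(1,1)\}$. The analysis rests on two
path-derived quantities:

- **DTW area** $A = \sum_k (x_k - y_k)$: the signed displacement of the
  warping path from the main diagonal. $A > 0$ means the reference leads
  the query in time. This is the test statistic.
- **Latency** $\mathrm{median}_k(x_k - y_k)\,/\,(f_s/1000)$ in ms: the
  descriptive effect size.

Inference is by resampling:

- `permutation_test()` — paired sign-flip permutation across participants
  (a fair coin flips each participant's condition pair; grand averages and
  the DTW area are recomputed per iteration; two-tailed p from absolute
  areas).
- `bootstrap_coupling()` — participants are resampled with replacement,
  and crucially the **same** bootstrap sample is used for both components in
  each repetition; each component's bootstrap grand average is aligned
  against its true observed grand average, and the paired area distributions
  are correlated (Pearson and Spearman). `exclude_outlier_pairs()` applies a
  ±k SD paired outlier rule, and `compare_correlations()` compares coupling
  strength between conditions via Fisher's Z.
- `noise_sweep()` — injects a known latency shift, adds EEG-spectrum noise
  (1/f plus alpha peak, `eeg_noise()`) at graded amplitudes, and reports how
  the latency estimate and the signal-to-noise ratio degrade.
- `generate_erp()` — a synthetic two-component, two-condition ERP generator
  with controllable latency jitter, cross-component coupling and noise,
  used for calibration and ground-truth recovery tests.

Plain-text I/O (`read_erp_dataset()`/`write_erp_dataset()`: headerless CSV
participant × time matrices with a JSON sidecar for sampling rate, time
origin and labels), `grand_average()`, `contra_ipsi_difference()` and a
zero-phase Butterworth `lowpass()` cover the standard plumbing. A thin
command-line wrapper with `synth`, `latency`, `coupling` and `simulate`
subcommands ships in `inst/cli/erpwarp.R`.

## Worked example

```r
library(erpwarp)

# synthetic study: 23 participants, two components, both delayed 20 ms in
# the "late" condition, component latencies coupled with unit slope
syn <- generate_erp(synth_spec(condition_shift_ms = 20), seed = 1)

permutation_test(syn$comp1$early, syn$comp1$late,
                 window = c(150, 400), n_perm = 2000, seed = 2)
#> <erp_permutation> observed area 1366, latency 18 ms, p = 0 (non-strict, 2000 flips)

bootstrap_coupling(syn$comp1$early, syn$comp2$early,
                   window1 = c(150, 400), window2 = c(250, 800),
                   n_boot = 2000, seed = 3)
#> <erp_coupling> 2000 paired bootstrap areas (n = 23 participants)
#>   Pearson r = 0.500, Spearman r = 0.508
```

The positive observed area says the early condition's grand average leads
the late one; the 18 ms latency estimate recovers the injected 20 ms shift
with the mild underestimation DTW is known for; no null area reached the
observed one in 2,000 flips. The bootstrap correlation ≈ 0.5 reflects the
generator's latency coupling; with `coupling_b = 0` it centers on zero.

Comparing coupling strength between two conditions:

```r
compare_correlations(0.33, 10000, 0.15, 10000)
#> <erp_cor_comparison> pearson r1 = 0.330 (n = 10000) vs r2 = 0.150 (n = 10000): z = 13.552, p = 7.674e-42
```

## Documentation

The methods vignette (`vignettes/erpwarp-methods.Rmd`) describes the model
and its assumptions, the default parameters and why, what the synthetic
generator does and does not emulate, and the numerical choices (tie-breaks,
p-value convention, noise synthesis, edge padding).
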