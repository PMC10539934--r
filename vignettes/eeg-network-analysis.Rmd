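---
title: "Resting-state EEG complexity, connectivity and graph analysis with eegconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG complexity, connectivity and graph analysis with eegconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package computes

`eegconn` implements a complete group-contrast analysis of resting-state
EEG on the 19-channel 10-20 montage, of the kind used to compare mild
cognitive impairment (MCI) against healthy controls (HC):

1. **Preprocessing** — zero-phase 0.1-50 Hz Butterworth band-pass of the
   continuous recording, segmentation into non-overlapping 2-s epochs,
   automatic amplitude/flatline artifact screening, and selection of the
   first 50 artifact-free epochs (100 s of data per channel).
2. **Spectral power** — DPSS multitaper PSD per epoch, averaged; band power
   in delta (0.1-4), theta (4-8), alpha (8-12), beta (12-30) and gamma
   (30-45 Hz); per-channel dB topography tables.
3. **Complexity** — multiscale sample entropy (m = 1, r = 0.25) and
   permutation entropy (m = 3) over coarse-graining scales 1-30, per channel
   on the concatenated selected epochs.
4. **Connectivity** — weighted phase lag index (wPLI) for all 171 channel
   pairs per band: `|mean Im S_xy| / mean |Im S_xy|`, pooling Hann-tapered
   per-epoch cross-spectra across epochs and in-band frequency bins.
   Whole-brain and frontal/central/parieto-occipital region means.
5. **Graph metrics** — binarisation at sparsity `S` (top `round(S * 171)`
   weights), swept 10-70% (efficiency) and 70-85% (small-world) in 1%
   steps; global/local/nodal efficiency, clustering coefficient,
   characteristic path length, and the small-world coefficient
   `sigma = (C/C_r)/(L/L_r)` against 100 degree-preserving rewired
   references.
6. **Statistics** — Shapiro-gated t / Wilcoxon comparisons, an exact
   rank-sum test at the study's sample sizes, Benjamini-Hochberg FDR with
   the study's correction families (19 electrodes within a band for power,
   complexity maps and nodal efficiency; 5 bands within a connection for
   wPLI; none for the efficiency and small-world sweeps), and 1,000-resample
   percentile bootstrap CIs.

Because no raw clinical EEG ships with the package, a synthetic cohort
generator (`cohort_spec()`, `generate_cohort()`) provides two-group data
with known ground truth, and every stage is tested against it.

## Running the pipeline

```{r}
library(eegconn)
cfg <- run_config(spec = cohort_spec(), seed = 42)
res <- run_pipeline(cfg, "out/")
report_summary(res)
```

EDF input is supported through `run_config(spec = NULL, edf_dir =, roster =)`
with a TSV roster (`subject`, `group`, `file`).

## The synthetic cohort: what it emulates and what it does not

Each subject is a 19 x (fs x duration) matrix built from four ingredients:

* **Band-limited background** per channel and band: Gaussian noise shaped by
  the squared magnitude response of the same 4th-order Butterworth cascade
  the preprocessing uses. Spatial weights reproduce the canonical resting
  topography (frontal delta dominance, occipital alpha/theta dominance).
  Default SDs (muV): delta 8, theta 3, alpha 7, beta 3, gamma 1.5.
* **Constant-lag coupling**: a shared band-limited source added to several
  channels, each at its own delay (`lag/(2 pi f_center)` seconds). A set of
  channels driven by one source forms a fully lagged-coherent clique; lags
  are staggered so every pairwise phase difference stays in
  `[0.14 pi, 0.85 pi]`, away from 0 and pi where the imaginary
  cross-spectrum vanishes.
* **Volume conduction**: instantaneous mixing `x <- (I + leakage (J - I)) x`
  (default leakage 0.05). Zero-lag mixing produces amplitude correlation but
  no wPLI — the robustness property the estimator is chosen for.
* **Broadband noise** (SD 3 muV); on the designated "entropy deficit"
  channels (C3/C4) of the MCI group the noise is AR(1) with coefficient
  0.95, making those channels more regular and lowering their sample
  entropy at low scales.

The default group effects encode the study-like stated world: 13 HC vs 12
MCI subjects, 104 s at 200 Hz. HC carries two seven-channel theta sources
spanning the scalp (bridged at Pz) at 5 muV; MCI carries a single frontal
seven-channel theta source at 4 muV. Consequences: MCI has lower whole-brain
theta wPLI (a coupling deficit), its reliable connections are concentrated
in one local clique (elevated clustering, markedly lower binarised global
efficiency at sparsity thresholds near the true edge count), and C3/C4
sample entropy is reduced.

**Effect-size calibration.** Studies of this design report no effect sizes
usable for calibration, so injected magnitudes are free parameters. They were fixed
once by a pilot power sweep at n = 13/12 over 10 seeds: the whole-brain
theta wPLI contrast and the theta global-efficiency contrast (minimum p
over sparsity 0.12-0.26) were each detected in 10/10 seeds. The acceptance
suite re-checks >= 80% detection on fresh seeds.

**What a green test does not establish.** The generator has no biophysical
forward model (no dipoles or leadfields), no realistic artifacts (blinks,
EMG), no 1/f background, and the coupling injection also adds theta band
power on the coupled channels — so band-power contrasts on the default
cohort are *not* null, unlike in the study. Detection of the injected
effects validates the pipeline's machinery, not any clinical claim.

## Numerical choices

* **Filtering**: the band-pass is a cascade of 4th-order high-pass and
  low-pass Butterworth filters in second-order sections, applied
  forward-backward. A direct-form 8-pole band-pass is numerically unusable
  with a 0.1 Hz edge at fs = 200. Zero-phase IIR filtering carries edge
  transients: the 0.1 Hz high-pass needs roughly 10 s per edge to settle,
  which is why gain tests measure the central span of a 100-s signal.
  Filtering is always applied to the continuous recording before epoching.
* **Multitaper**: DPSS tapers from the tridiagonal commuting eigenproblem,
  time-half-bandwidth 2, 3 tapers per 2-s epoch; one-sided density scaled so
  that the integral over [0, fs/2] matches the signal variance. "Band power"
  defaults to the mean density in the band (the integral is an option);
  note the mean is not monotone under band inclusion, the integral is.
* **Sample entropy**: Chebyshev distance, self-matches excluded, both
  template sets of size N - m; tolerance r = 0.25 x SD of the
  coarse-grained series at each scale (option: SD of the original series,
  the classic convention under which white noise yields a decreasing
  multiscale curve; under the per-scale convention it is flat). Undefined
  (no matches) returns NaN; a constant series returns 0.
* **Permutation entropy**: ordinal patterns with ties broken by order of
  appearance (stable `order()`); ties have probability 0 for continuous
  data.
* **wPLI**: epochs are demeaned, Hann-tapered, FFT'd; cross-spectral terms
  are pooled across epochs *and* in-band bins before the ratio (per-bin
  estimates averaged across the band behave similarly but with a higher
  floor at fixed data). The estimator has a positive noise floor of order
  `sqrt(pi / (2 n_eff))` under independence — about 0.08 on the whole-brain
  mean with 50 epochs — which decreases with epoch count; tests assert the
  floor behaviour rather than exact zero. All-zero imaginary parts (e.g.
  identical channels) define wPLI = 0.
* **Binarisation**: `N = round(S * n(n-1)/2)` strongest weights; ties at
  the N-th weight broken by lexicographic (row, column) order —
  deterministic and documented.
* **Path length on disconnected graphs**: averaged over connected pairs
  (default) or `Inf` (`disconnected = "inf"`). The inverse-distance
  efficiency metrics are the primary integration measures, so the sweep
  never propagates infinities.
* **Random references**: degree-preserving double edge swaps (10 x edges
  swap attempts, seed-controlled); graphs admitting no swap (stars) fall
  back to edge-count-matched Erdos-Renyi with a warning.
* **Exact rank-sum test**: dynamic programming over doubled midranks gives
  the exact two-sided permutation p-value even with ties for combined
  n <= 25 (the study's scale); larger samples use the tie-corrected normal
  approximation without continuity correction.
* **Seeds**: all randomised stages (synthesis, references, bootstrap) draw
  child seeds derived from the master seed, so partial re-runs reproduce.

## Design choices where the source was open

* Epochs are concatenated (100 s per channel) before entropy estimation
  rather than averaging per-epoch entropies; 2-s epochs leave too few
  coarse-grained samples at scale 30 for stable sample entropy.
* Group statistics are computed on linear band power; dB is used only for
  display tables.
* The complexity correction family is "19 electrodes within an estimator at
  the tested scale" (scale 4 by default), by analogy with the per-band
  electrode families used for power and nodal efficiency.
* Pipeline nodal-efficiency group tests run at the 20% sparsity threshold
  (the most diagnostic threshold in this literature); the full nodal sweep
  is still written out.
* Efficiency and small-world sweep p-values are deliberately left
  uncorrected across grid points, mirroring the study's analysis; treat a
  single significant grid point with caution.

## Known limitations

* The EDF reader covers the plain 16-bit EDF profile (no EDF+ annotations,
  one sampling rate across kept channels).
* Visual artifact rejection is replaced by peak-to-peak/flatline screening;
  no ICA, interpolation or re-referencing.
* The small-world sweep at 100 references per grid point is the slow path;
  reduce `n_refs` or the grid for exploratory runs.
* Sample sizes of 12-13 give exact rank-sum p-values with a coarse
  resolution floor (minimum two-sided p about 2e-7, but ties coarsen it);
  bootstrap CIs at n = 12 are percentile, not BCa.
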