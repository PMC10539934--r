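# eegconn

Resting-state EEG complexity, connectivity and graph analysis for
two-group clinical contrasts (e.g. mild cognitive impairment vs healthy
controls) on the 19-channel international 10-20 montage.

## The scientific problem

Early cognitive decline is hard to see in raw EEG band power, so studies of
MCI combine several complementary descriptions of the resting signal:

* **Spectral power** per canonical band (delta 0.1-4, theta 4-8, alpha
  8-12, beta 12-30, gamma 30-45 Hz), estimated by the DPSS multitaper
  method on 2-s epochs.
* **Multiscale entropy** — sample entropy
  `SampEn = -ln( C_{m+1}(r) / C_m(r) )` (m = 1, r = 0.25 x SD, Chebyshev
  distance, self-matches excluded) and permutation entropy
  `H = -sum p(pi) log2 p(pi)` (motif length 3), computed on coarse-grained
  series at scales tau = 1..30.
* **Functional connectivity** — the weighted phase lag index for channels
  x, y with cross-spectrum S_xy:

  `wPLI = | E[ Im S_xy ] | / E[ | Im S_xy | ]`

  pooled over epochs and in-band frequency bins. wPLI weights phase
  differences by the magnitude of the imaginary cross-spectrum, so zero-lag
  (volume-conducted) mixing contributes nothing.
* **Graph metrics** on the binarised 19 x 19 wPLI matrix at a swept sparsity
  threshold S (top `round(S x 171)` edges): global efficiency
  `E_glob = (1/(n(n-1))) sum_{i != j} 1/d(i,j)`, local and nodal
  efficiency, clustering coefficient `C_i = 2 e_i / (k_i (k_i - 1))`,
  characteristic path length, and the small-world coefficient
  `sigma = (C/C_r) / (L/L_r)` against 100 degree-preserving random
  references (`sigma > 1` = small world).
* **Group statistics** — Shapiro-gated t / exact Wilcoxon rank-sum tests,
  Benjamini-Hochberg FDR applied per band across the 19 electrodes (power,
  complexity, nodal efficiency) or per connection across the 5 bands
  (wPLI), and percentile bootstrap confidence intervals.

Raw clinical recordings are rarely shareable, so the package includes a
synthetic cohort generator with known ground truth (band-limited
oscillations, constant-lag coupling, zero-lag volume-conduction mixing,
tunable group effects); every pipeline stage is tested against it. See the
methods vignette (`vignettes/eeg-network-analysis.Rmd`) for the model and
all numerical choices.

## Worked example

```r
library(eegconn)

# small-world classification of a canonical Watts-Strogatz graph
ws  <- make_graph_fixture("watts_strogatz", 100, list(k = 4, p = 0.1), seed = 1)
sig <- small_world_sigma(ws, n_refs = 100, seed = 2)
round(sig, 2)
#> [1] 9.17          # sigma > 1: small-world topology

# one synthetic control subject, preprocessed
spec <- cohort_spec(n_hc = 5, n_mci = 5, duration = 40, seed = 42)
rec  <- generate_subject(spec, "HC", 1)
rec
#> <eeg_recording> hc01 [HC]: 19 ch x 8000 samples @ 200 Hz (40.0 s)
es <- preprocess_subject(rec, n_keep = 15)   # 0.1-50 Hz, 2-s epochs
es
#> <epoch_set> hc01 [HC]: 15 epochs x 19 ch x 400 samples (2 s @ 200 Hz)

# theta-band wPLI and graph metrics at sparsity 0.15
cm <- connectivity_matrix(es, eeg_bands("theta"))
cm
#> <connectivity_matrix> theta band, 19 channels, 15 epochs, mean 0.320
round(region_mean(cm, "frontal"), 3)    # mean over the 21 intra-frontal pairs
#> [1] 0.21
g <- binarize_top_n(cm, 0.15)           # top round(0.15 * 171) = 26 edges
c(edges = graph_edge_count(g),
  e_glob = round(global_efficiency(g), 3),
  e_loc  = round(local_efficiency(g), 3))
#>  edges e_glob  e_loc
#>     26  0.293  0.412

# multiscale sample entropy of channel C4
mc <- multiscale_curve(concat_channel(es, "C4"), "sample", scales = c(1, 4, 8))
mc
#>   scale     value
#> 1     1 0.8180402
#> 2     4 1.6568857
#> 3     8 1.8451472
```

The whole-brain theta wPLI of 0.320 reflects this subject's injected
lagged theta coupling; 26 edges is exactly `round(0.15 x 171)`; the
entropy curve rises toward coarse scales because the signal's broadband
noise is progressively averaged out relative to its band-limited structure.

## Full pipeline

```r
cfg <- run_config(spec = cohort_spec(), seed = 42)  # 13 HC vs 12 MCI, 104 s
res <- run_pipeline(cfg, "out/")    # TSV tables + manifest.json in out/
report_summary(res)                 # significant findings per family
```

A command-line wrapper with `simulate` / `analyze` / `report` subcommands
is installed at `inst/cli/eegconn-cli.R`.

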