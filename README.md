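# ildtuning

Analysis of interaural level difference (ILD) tuning and its spatial
organization in two-photon calcium imaging data from auditory cortex.

Microelectrode studies sample cortex sparsely; two-photon imaging of a
genetically encoded calcium indicator measures most neurons within a
~250 µm field at known positions, which makes it possible to ask not
only *how* single neurons encode the principal sound-localization cue of
small mammals — the level difference between the two ears — but *where*
neurons with similar binaural properties sit relative to one another.
`ildtuning` provides the full analysis chain for such experiments, for
researchers analyzing their own recordings or evaluating the methods on
simulated ground truth:

- **Signal extraction** — high-pass filtering (0.02 Hz, zero-phase),
  percentile-slice baseline F0, ΔF/F0, neuropil correction
  (`corrected = cell − r·neuropil`, r = 0.6), and per-trial responses
  defined as the stimulation-window peak minus the pre-stimulus-window
  peak (14 frames each at ~30 Hz).
- **Per-neuron statistics** — paired one-tailed t-tests for
  responsiveness (α = 0.01), one-way ANOVA across 7 ILDs per ABL for
  ILD sensitivity (α = 0.05), peak ILD, response slopes, and the
  weighted ILD preference (centroid)
  `ILD_w = Σ ILD_i·r̄_i / Σ r̄_i`; two-way frequency × level ANOVA,
  frequency response areas, best frequency with a 3-SD validity rule,
  tonotopic-gradient orientation by axis rotation, and the
  coefficient of BF variation (SD of log2 BF).
- **Binaural categories** — EO / OE / EE / OO-F monaural classes and the
  binaural interaction index BII = diotic / (contra + ipsi), with
  facilitation above 1.2, inhibition below 0.8, and the EE/O occlusion
  rule.
- **Population decoding** — PCA of the normalized neurons × (ILD × ABL)
  response matrix, and an opponent-channel decoder that classifies
  single-trial ILD from the difference between contra- and
  ipsi-preferring population responses with leave-one-out
  cross-validation, reporting the mean unsigned error (MUE) versus
  population size.
- **Spatial statistics** — pairwise signal and noise correlations with
  bootstrap shuffle nulls, correlation-versus-distance fits, and the
  bootstrapped clustering test (local ≤150 µm pairs against resampled
  distant pairs, 5th-percentile rule) for ILD preferences, best
  frequencies, and binaural categories.
- **Synthetic experiments** — a generator that emulates the whole
  protocol (stimulus schedule, GCaMP-like transients, neuropil
  contamination, shared trial-to-trial noise, planted tuning, binaural
  classes, tonotopic gradients, spatial clusters) with seeded,
  bit-reproducible output, so every stage is testable without data.

## Worked example

Simulate a 40-neuron session (7 ILDs × 3 ABLs × 12 noise repetitions,
monaural noise, 18 tones × 4 levels × 10 repetitions) and run the whole
pipeline:

```r
library(ildtuning)

exp <- simulate_experiment(n_neurons = 40, seed = 7)
cfg <- default_config(decoder_n_rep = 100, decoder_sizes = c(5, 10, 20),
                      seed = 7)
report <- run_pipeline(exp, cfg)

report$summary$responsiveness
#>   abl_db pct_responsive pct_ild_sensitive
#> 1     40           77.5              67.5
#> 2     60           80.0              70.0
#> 3     80           80.0              67.5
```

Most simulated neurons respond to noise bursts and are ILD-sensitive at
each ABL — the generator's default population is strongly tuned. The
binaural category mix is dominated by contra-driven/inhibited (EO/I) and
binaurally facilitated (OO/F) cells, as planted:

```r
head(subset(report$summary$categories, abl_db == 60))
#>   abl_db category  n       pct
#> 3     60     EE/O  2  7.692308
#> 6     60     EO/F  1  3.846154
#> 9     60     EO/I 10 38.461538
#> 12    60     EO/N  2  7.692308
#> 16    60     OE/I  2  7.692308
#> 19    60     OO/F  9 34.615385
```

The opponent-channel decoder classifies single-trial ILD better as the
sampled population grows (errors in dB; chance is ~22.9 dB):

```r
report$decoder$curve
#>   size    mue_db    mue_sd mue_normalized
#> 1    5 10.554365 1.4248640      0.1759061
#> 2   10  9.234921 1.0732024      0.1539153
#> 3   20  8.529762 0.6643841      0.1421627

round(report$decoder$pca$var_explained[1:3], 3)
#> [1] 0.535 0.225 0.097
```

The first three principal components of the population ILD × ABL
response matrix capture ~86% of the variance. Spatial results live in
`report$spatial`: with the default generator (no planted clusters) the
ILD-preference cluster test is, as expected, not significant
(`report$spatial$ild$significant` is `FALSE`).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/run_pipeline.R` (`simulate`, `validate`, `all`
subcommands); experiments are stored as plain-text directories
(CSV matrices + YAML parameters) via `write_experiment()` /
`read_experiment()`.

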