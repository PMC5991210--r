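---
title: "From fluorescence traces to binaural maps: the ildtuning methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From fluorescence traces to binaural maps: the ildtuning methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ildtuning)
```

`ildtuning` implements a complete analysis chain for two-photon calcium
imaging studies of interaural level difference (ILD) coding in auditory
cortex, together with a synthetic-experiment generator that supplies
ground truth for every stage. This vignette explains the models and
procedures, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the synthetic tests do and do not
establish about real data.

## The experiment the package models

One imaging session presents, to an anesthetized head-fixed animal,
100 ms broadband noise bursts at 7 ILDs (−30 to +30 dB in 10 dB steps;
negative = louder at the contralateral ear) crossed with 2–3 average
binaural levels (ABLs, 40/60/80 dB SPL), the same noise monaurally to
each ear, and diotic pure tones on an 18-frequency log grid
(1.9–50 kHz, 0.277-octave steps) at four levels — 12 repetitions of each
noise stimulus and 10 of each tone, in pseudorandom order within
separate noise and tone blocks, at 0.65 Hz under a ~30 Hz frame clock
(46 frames per trial, the stimulus spanning ~3 frames). `stimulus_spec()`
encodes these defaults; `build_stimulus_schedule()` realizes a seeded
schedule in which every stimulus–repetition combination occurs exactly
once. The ABLs are interleaved with ILDs within the noise block; the
protocol leaves the block sub-structure open and interleaving is the
least structured choice.

A note on the tone grid: 18 tones spanning 1.9–50 kHz force
log2(50/1.9)/17 ≈ 0.277-octave spacing; a coarser 0.6-octave spacing
sometimes quoted for such protocols is inconsistent with those
endpoints, so the 0.277-octave grid is used.

## Signal extraction

For each neuron the raw fluorescence trace is processed as:

1. **High-pass filter**, 0.02 Hz cutoff. Realized as subtraction of a
   centred moving-average low-pass (window = frame rate / cutoff frames,
   reflective padding) with the trace mean restored. A moving-average
   subtraction is zero-phase, which matters because responses are peak
   differences in short windows: a causal filter would shift transient
   peaks relative to stimulus onset. At 30 Hz this passes a 1 Hz
   sinusoid with gain > 0.99 and attenuates a 0.005 Hz sinusoid below
   0.5. Traces shorter than three filter time constants are left
   unfiltered with a warning.
2. **Baseline F0**: the median of the samples whose rank percentile lies
   in (10, 70] — the top 30% of values is excluded so calcium transients
   do not inflate the baseline, the bottom 10% guards against downward
   artifacts. The rank bounds are computed as the smallest i with
   i/n > 0.10 and the largest with i/n ≤ 0.70, guarded against
   floating-point edge cases at exact multiples. F0 is computed after
   filtering, following the processing order of the narrative the
   pipeline follows; the alternative order differs only through the
   filter's effect on the percentile slice.
3. **ΔF/F0** = (F − F0)/F0, and **neuropil correction** on ΔF/F traces:
   corrected = cell − r × neuropil, r = 0.6 by default.
4. **Per-trial responses**: pre-stimulus peak = max ΔF/F0 over the 14
   frames before onset (~500 ms), stimulation peak = max over the 14
   frames from onset (onset included in the post-window only);
   response = post − pre, which cancels slow local fluctuations. A
   window-sum statistic is available behind
   `extract_responses(statistic = "sum")`, default off.

## Per-neuron statistics

*Responsiveness*: one paired one-tailed t-test per stimulus (post-window
peak > pre-window peak across repetitions), alpha 0.01; a neuron is
noise- (tone-) responsive if any ILD (frequency) is significant. When
the paired differences have zero variance the t statistic is undefined;
a consistent strict increase is reported as p = 0 and anything else as
p = 1, which makes noise-free synthetic data classifiable.

*ILD sensitivity*: one-way fixed-effects ANOVA across the 7 ILDs,
alpha 0.05, separately at each ABL. For sensitive neurons the package
reports the **peak ILD** (argmax of the trial-averaged curve; ties broken
toward the most contralateral ILD), the six **slopes** between contiguous
ILDs with the steepest-slope midpoint (steepest by absolute value), and
the **weighted ILD preference (centroid)**

$$\mathrm{ILD}_w = \frac{\sum_i \mathrm{ILD}_i \, \bar r_i}{\sum_i \bar r_i}.$$

The centroid denominator deserves a flag: the printed form of this
equation in the literature this package follows divides by
$\sum_i \mathrm{ILD}_i$, which is identically zero for a symmetric ILD
set and cannot be intended; the package uses the conventional
response-sum denominator, which is what "centroid" means. Negative mean
responses are floored at zero before the centroid (suppression should
not flip the preference sign; `floor_negative = FALSE` disables this),
and a neuron whose floored responses sum to zero has an undefined
centroid and is flagged rather than silently dropped.

*Frequency tuning*: the frequency response area (FRA) is the freq × level
matrix of trial-mean responses; a 3-point running average along frequency
(truncated and renormalized at the edges) is provided for display only —
statistics always use the unsmoothed matrix. Sensitivity is a two-way
ANOVA on frequency and level (type-II sums of squares, so unbalanced
designs are handled; on the balanced default grid this equals the
classic two-way ANOVA). For frequency-sensitive neurons the **best
frequency (BF)** is the argmax of the level-averaged response (ties to
the lowest frequency, logged), and is *valid* only if the mean response
at BF is at least 3 SDs above the mean pre-stimulus level, both computed
from the neuron's tone-trial pre-window peaks — the protocol does not
define "prestimulus response" precisely, and the pre-window peaks are
the quantity the response statistic is already built on.

*Tonotopy*: `tonotopic_gradient()` correlates log2(BF) with the position
projection onto an axis rotated in 1° steps through 360°; the strongest
negative correlation marks the tonotopic axis. The profile satisfies
r(θ) = −r(θ+180°) exactly, so the axis is defined up to that sign
convention. `bf_variation()` is the SD of log2(BF) in octaves.

## Binaural categories

Using the monaural contralateral, monaural ipsilateral and diotic (0 dB
ILD) stimuli at one ABL: significance of each response (paired t-test,
alpha 0.01) yields the monaural class — EO (contra only), OE (ipsi
only), EE (both), OO/F (diotic only: binaural facilitation with no
monaural response), or unresponsive. For EO/OE/EE the **binaural
interaction index** BII = diotic / (contra + ipsi) (means floored at
zero; ratio categories presuppose nonnegative magnitudes) refines the
class: BII > 1.2 facilitation (/F), BII < 0.8 inhibition (/I), the
closed band [0.8, 1.2] no interaction (/N). An EE neuron with BII < 0.8
whose diotic response still exceeds 80% of the dominant-ear response
shows occlusion (EE/O). The remaining EE case — BII < 0.8 with a diotic
response at or below that bound — is not named in the taxonomy this
follows; it is labelled EE/I and reported separately so totals stay
auditable. Boundary BIIs of exactly 0.8 or 1.2 land in the
no-interaction band. Classification runs separately per ABL.

A trial-history caveat that the synthetic experiments expose: with a
GCaMP6m-like 600 ms decay at 0.65 Hz presentation, the tail of the
previous trial's transient raises every pre-window peak by a
stimulus-independent amount. Because that constant enters the BII
numerator once but the denominator twice, measured BIIs are biased
upward (a planted BII of 1.0 measures ≈ 1.3 in the noise-free limit).
This is a deterministic property of slow indicators under fast
presentation, not noise; the exact-recovery checks therefore use the
generator's fast-indicator kernel (20 ms rise, 250 ms decay), under
which all planted categories are recovered exactly. Analyses of real
GCaMP6m data inherit this bias and should read BII boundaries
accordingly.

## Population analyses

**PCA** operates on the neurons × (7 ILD × 3 ABL) matrix of trial-averaged
responses, each row normalized by its own maximum so high-gain neurons
do not dominate the variance; rows with non-positive maxima are excluded
and logged. Components are centred, unscaled; variance fractions sum
to 1 and the eigenvector coefficients are reshaped to ILD × ABL for
inspection.

**Opponent-channel decoding.** Each noise-responsive neuron's single-trial
responses, pooled across ABLs, are regressed on signed ILD; significant
(p < 0.05) slopes define monotonic neurons, negative slopes the
contra-preferring channel, positive the ipsi-preferring one. Normalized
responses (each neuron divided by its maximum trial-averaged per-ILD
response) are averaged within channels, and the contra − ipsi difference
is the opponent value of a trial. A trial's ILD is decoded as the ILD
whose mean opponent value — computed from all *other* trials
(leave-one-out) — is nearest; ties break toward the smaller |ILD|
(logged), a deliberately conservative choice that favors midline
confusions over lateral ones. Performance is the mean unsigned error
(MUE) in dB, also normalized by the maximal possible single-trial error,
taken as 60 dB (the full −30 to +30 span). `decoder_curve()` repeats the
decode over random neuron subsamples (without replacement) at each
population size — 1000 resamples in the reference protocol,
configurable — requiring at least one neuron per channel (degenerate
draws are redrawn and counted). Neurons may be pooled across fields;
trial-to-trial noise correlations are known to have little effect on
this decoder, which is what justifies non-simultaneous pooling.

**Signal and noise correlations.** For a simultaneously imaged pair, the
noise correlation is the Pearson correlation of per-trial responses
after subtracting each neuron's condition mean; the signal correlation
is the correlation of the condition-mean vectors minus the noise
correlation, so by construction signal + noise equals the raw
correlation of trial-averaged responses. Bootstrap shuffle nulls redraw
responses with replacement within condition (noise mode) or across all
stimuli (signal mode), 1000 iterations by default; observed vs null
means are compared by a paired t-test across pairs at alpha 0.01.
Correlation-versus-distance relationships are ordinary least-squares
fits per cortical axis.

**Spatial clustering.** The preference distance of a pair is
|value_a − value_b| (weighted ILD in dB; BF in octaves via log2; binaural
categories coded EO/I = −1, EO/F = 0, OO/F = 1, the three dominant
classes). The observed statistic is the mean over all local pairs
(2D separation ≤ 150 μm in the rostro-caudal × dorso-ventral plane —
depth is excluded, matching 2D cortical maps; 100/200/250 μm bins are
config options). The null draws the same number of distant (>150 μm)
pairs 1000 times — without replacement when enough distant pairs exist,
with replacement otherwise — and clustering is significant when the
observed mean falls strictly below the 5th percentile of the bootstrap
means (ties therefore never reject). ILD and category clustering are
restricted to neurons with valid BF ≥ 10 kHz, since free-field ILDs from
lower frequencies are negligible for small heads.

A calibration caveat the package's own simulations establish: local
pairs share neurons, so their preference distances are positively
correlated, and the observed local mean is correspondingly more variable
across fields than the bootstrap's independent subsample means. Under a
spatially random null this procedure therefore rejects more than its
nominal 5% (≈10–25% depending on geometry and neuron count). The
procedure is implemented exactly as published — alternative spatial
statistics are out of scope — but significant clustering calls from it
should be read with that anticonservatism in mind, and the package's
acceptance suite reports the measured false-positive rate rather than
asserting nominal calibration.

## The synthetic-experiment generator

`simulate_experiment()` draws a ground-truth population
(`synth_neurons()`): tuning types (45% monotonic-contra, 15%
monotonic-ipsi, 25% peaked, 15% untuned — a contralateral-dominant
mixture typical of rodent A1), a binaural class per neuron with the
OO/F- and EO/I-heavy mixture seen in such populations, log-uniform BFs
over 4–45 kHz for 70% of neurons, V-shaped FRAs (0.5–1.2 octaves,
broadening with level), spontaneous rates of 0.5–3 spikes/s and evoked
gains of 30–90 spikes/s, and 15% unresponsive cells. Binaural classes
are made *internally consistent*: the diotic evoked rate equals the
class's target BII times the summed monaural rates (targets 1.5 / 1.0 /
0.5 for /F, /N, /I; 0.47 and 0.26 for EE/O and EE/I), so the classifier
can be validated against planted truth.

Fluorescence is synthesized per neuron as inhomogeneous Poisson spikes
at the expected rate (stimulus-evoked rate during the ~3 stimulus
frames, baseline elsewhere), convolved with a double-exponential kernel
(defaults 50 ms rise, 600 ms decay — GCaMP6m-like; configurable because
indicator parameters vary), scaled at 0.18 ΔF/F per spike. The measured
trace adds: a field-common neuropil signal (70% of the population-mean
ΔF/F plus a slow AR(1) background) mixed in at ratio r = 0.6, a slow
sinusoidal drift (5% of F0, 120 s period — removed by the high-pass),
frame-wise white noise (SD 0.03 ΔF/F), and a field-common per-trial
latent that multiplies each neuron's evoked response (weight =
`noise_share`), which is what induces trial-level noise correlations.
A per-neuron neuropil trace is emitted so the correction path is
exercised end-to-end. `deterministic = TRUE` replaces Poisson counts by
their expectation; `sim_params_noise_free()` silences every noise source
for exact-recovery checks. All randomness flows from one root seed
through named substreams (schedule, neurons, layout, spikes, noise,
latent), so identical configurations regenerate bit-identical
experiments.

`plant_spatial_structure()` places neurons uniformly in the field and can
impose a tonotopic gradient (log2 BF decreasing linearly along a stated
axis plus jitter) or ILD-preference clusters (each neuron takes its
nearest cluster's preferred ILD plus a stated spread, realized as peaked
tuning).

What the generator does *not* emulate: pixel-level movies, motion
artifacts, ROI segmentation errors, nonlinear indicator saturation,
bursting statistics beyond Poisson, or frame-to-frame correlated
measurement noise. Passing tests therefore establish that the analysis
chain is arithmetically correct, statistically calibrated and able to
invert the generative model it assumes — not that real cortical data
satisfy that model.

## Problem sizes and numerical choices in the validation suite

The package validates itself at sizes chosen to give tight Monte-Carlo
error at desk scale: 1000 fuzz cases per arithmetic oracle; 10,000 null
tests per significance test (the two-way ANOVA null uses a reduced
6 × 3 × 5 grid — type-I rates do not depend on design size); one
300-neuron synthetic session for tuning recovery, run in the
stated-SNR regime (expected spike counts, measurement noise giving
per-trial response noise near a tenth of the response, BFs planted on
the tone grid with 0.4–0.7-octave FRAs — exact grid-argmax BF recovery
is information-theoretically impossible for tuning much broader than the
0.277-octave grid step at that SNR, since neighbor-frequency response
differences fall below the noise floor); decoder curves at 100 resamples
per population size (1000 in the reference protocol); 400 spatially
random and 200 planted-cluster fields for the cluster test; and 200
jittered fields (1 mm² window, 100 neurons, 0.003 oct/μm at 37°, 0.35
octave BF jitter) for gradient recovery.

Other numerical conventions, gathered in one place: peak-ILD ties break
contralateral; BF ties break to the lowest frequency; BII boundaries
belong to /N; decoder reference ties break toward smaller |ILD|;
cluster-test ties at the 5th percentile do not reject; zero-variance
paired tests return p ∈ {0, 1} by the sign of the constant difference;
all-equal inputs to ANOVA return an undefined p and a negative flag.

## Known limitations

The cluster-test anticonservatism and the slow-indicator BII bias
described above are the two substantive caveats. Beyond those: the
centroid flooring makes strongly suppressed neurons' preferences
undefined rather than extrapolated; the decoder assumes channel
assignments estimated from the same dataset it decodes (as in the
protocol it follows — channel estimation is not cross-validated, only
the reference curves are); and experiment I/O uses a plain-text
directory layout (CSV matrices + YAML parameters) as its interchange
format.
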