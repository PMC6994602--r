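---
title: "Methods: synthetic ECoG face-processing analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic ECoG face-processing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Intracranial (ECoG) recordings measure voltage from electrodes resting
directly on the cortical surface, at millisecond resolution and millimetre
precision. In category-selective visual cortex, the power of the
high-frequency broadband signal (HFB, 70-177 Hz) tracks local population
firing and is the workhorse marker for asking *where* and *when* a cortical
site engages during face processing. This package implements the complete
analysis chain for such experiments — preprocessing, univariate site
classification, multivariate decoding, response-onset-latency (ROL)
estimation and stimulation-outcome statistics — together with a synthetic
recording generator, because the patient recordings such analyses are
normally run on cannot be shared. Every stage is therefore testable end to
end on data whose ground truth is known.

## The synthetic generator

`simulate_raw()` builds a raw-like recording for a task design in which
images from eleven categories (four face categories, four headless-body
categories, limbs, objects, places) are presented for 300 ms with a 400 ms
inter-stimulus interval; 25 images per category presented twice gives the
reference design of 550 stimulus events, 50 per category. Attention catch
trials (a red "###" requiring a key press) are interleaved and always
excluded from analysis.

Each channel carries:

* **1/f-like background** — an AR(1) process (coefficient 0.97, spectral
  exponent near -2), scaled to 8 uV SD. The choice of an autoregressive
  pink-noise model is ours; it gives the notch and wavelet stages a
  realistic broadband background to work against.
* **a high-gamma floor** — band-limited (70-170 Hz) Gaussian noise at
  1.5 uV SD, so that every site has measurable baseline HFB power.
* **optional 60 Hz line noise**, to exercise the notch stage.

A *planted effect* multiplies the high-gamma floor of one site by a
trapezoidal envelope time-locked to that site's preferred categories: the
plateau gain is `10^(dB/20)` for the requested dB amplitude, beginning
`latency_ms` after stimulus onset. Because the pink background also leaks
a little power into the HFB range, the realized dB response is somewhat
below the nominal planted value; tests therefore assert recovery of the
*site* and of latency *differences*, not of the exact dB number.

`simulate_band_power()` generates the same structure one stage later —
trials x sites x time arrays of baseline-rescaled dB — and is used where
the raw-signal path would only add runtime: its background is temporally
smoothed Gaussian noise (20 ms FWHM, 1 dB SD by default), its responses
trapezoidal dB ramps. What neither generator emulates: spatially
correlated noise across electrodes, interictal artifacts beyond simple
amplitude excursions, eye movements, or any retinotopic structure. Passing
tests therefore demonstrate that the *analysis machinery* is correct and
calibrated, not that it is robust to every pathology of clinical data.

### The ramp semi-simulation

The signal-to-noise sweep used to validate onset detection injects, into
every condition-A trial, a ramp whose terminal amplitude is

    X_A,eff = X_A + SNR_in x std(mean trace of B trials),

with `SNR_in` varied from 2 to 10 in steps of 0.5. The source of this
calibration gives the ramp "a slope of 3 until 500 ms" without units; we
interpret the slope as terminal-amplitude units per window length, i.e. the
injected increment reaches its terminal value after `window/slope` and
plateaus until the window's end (500 ms by default). Both the slope and the
window are configurable. `std` is taken over time of the trial-averaged
reference trace, the literal reading of the formula; per-trial pooling is
available by computing the reference differently before the call.

## Preprocessing

Stages run in a fixed order — downsample (anti-aliased, to 1 kHz), notch
filter (zero-phase Butterworth band-stops at 57-63, 117-123, 177-183 Hz),
channel quality control, common-average re-reference over retained
channels, epoching to [-200, 700) ms with baseline correction over
[-200, 0) ms, amplitude-based artifact rejection (|V| > 100 uV), Morlet
wavelet band power. Swapping quality control and re-referencing changes
the result (a bad channel would contaminate the average), which a
regression test guards.

Channel QC rejects a channel whose variance exceeds five times (or falls
below one fifth of) the across-channel mean variance, or whose count of
jumps (absolute first differences > 100 uV) exceeds three times the mean
count. The mean (not median) matches the rule's original wording; both
factors are configurable.

Band power uses complex Morlet wavelets at 1 Hz steps (seven cycles at and
above 70 Hz, five below), skipping frequencies inside the notch stopbands
— the HFB grid is 70-116 and 124-176 Hz. Per frequency, the log10 power of
each trial and channel is rescaled by subtracting its mean log10 power
over the [-100, 0) ms baseline, multiplied by 10 to give dB, then averaged
over the band's bins. This makes the baseline-window mean *exactly* 0 dB
before smoothing (the suite asserts it to 1e-6), and an amplitude doubling
of a within-band carrier comes out as `10*log10(4) = 6.02` dB. Smoothing
is a 50 ms FWHM Gaussian with reflection padding; the unsmoothed signal is
kept alongside because onset detection must not see the smoothing kernel.
All analysis windows are closed (`[150, 500]` ms spans 351 samples at
1 kHz, the decoding feature length); extraction windows are half-open.

## Site classification

Sites are classified with non-parametric permutation tests (sign flips for
paired contrasts, label shuffles for unpaired; `p = (k+1)/(N+1)` so p is
never zero; defaults 50,000 / 10,000 permutations, reduced in the demo
configuration):

* **active** — some category's mean response in [150, 500] ms differs from
  its own [-100, 0) ms baseline (two-sided paired test). The FDR family
  here is the full site x category grid: controlling per category leaves
  the probability of *any* false activity flag near `1 - 0.95^11` under
  the global null, which would defeat the calibration the classifier is
  meant to have. With the joint family the any-flag rate on signal-free
  data stays at the nominal 5%, which the acceptance suite verifies over
  100 simulated datasets.
* **face-selective** — among active sites, pooled face responses exceed
  pooled non-face responses (one-sided unpaired test, FDR over the active
  sites). **Human-face-selective** is the same contrast with human faces
  alone. One-sided tests implement "significantly higher"; the activity
  test stays two-sided.
* **task-active** — active but in neither selective class.

The *selectivity score* of a site — the quantity correlated with position
and latency downstream — is defined as the windowed mean dB difference
between human faces and pooled non-faces. The source material colors its
maps by exactly this difference without naming a formula, so the package
adopts it as the score.

Per-test RNG streams are derived from one master seed by counter, making
the classification invariant to site and trial ordering (tested).

## Decoding

Human-face versus non-face decoding uses a linear kernel (epoch
dot-products) over features = sites x the 351 window samples, a
soft-margin SVM on the precomputed kernel — trace-normalized to unit mean
diagonal so that the C grid spans the same effective regularization range
whatever the feature scale — and stratified 5-fold outer
cross-validation with a 4-fold inner selection of C from
{0.01, 0.1, 1, 10, 100} by inner balanced accuracy (ties toward the
smallest C). Non-face epochs are subsampled once per model to match the
human-face count, spread as evenly as possible over the seven non-face
subcategories. Balanced accuracy is the mean of the two class
sensitivities. Model variants differ only in their site sets: all sites;
all sites minus the human-face-selective ones; and 499 random subsets of
face-selective plus task-active sites of the same size as the second
variant, each containing at least one face site (drawn by rejection so the
proportion of face sites varies naturally).

The sparse model builds one kernel per site (trace-normalized so sites
with larger variance do not dominate — switchable) and learns a convex
combination by alternating SVM fits with reduced-gradient steps on the
weights, projected onto the probability simplex (the projection produces
exact zeros, hence sparsity). Convergence: weight change below 1e-4 or a
relative objective change below 1e-6, within 200 iterations; the step size
is carried across iterations with backtracking, the inner C search uses a
coarser 25-iteration budget since it only ranks C values, and the SVM
fits inside the weight loop run at a relaxed KKT tolerance (0.05) because
the loop has its own convergence control — the selected C and the final
weights are unchanged by this, at an order of magnitude less compute.
Kernel additivity (the all-sites kernel equals the sum of per-site
kernels) is asserted exactly. Fold-level kernel weights are averaged into
the contribution map; sparsity is the fraction of non-null contributions.

Stratification of folds is not stated in the source protocol but is
required for balanced accuracy to be well-behaved in every fold, so folds
are stratified by class. The non-face subsample is drawn once per model,
not per fold.

## Response onset latency

Per trial, the unsmoothed HFB trace is peak-normalized (peak searched in
[0, 600] ms so baseline artifacts cannot define the peak) and scanned with
30 ms bins advancing 2 ms; the onset is the start of the first run of 25
consecutive bins whose means strictly exceed threshold, so a flat zero
trace is undetected. Bins are half-open `[t, t+30)` aligned to stimulus
onset: a noiseless step at 200 ms is detected at 172 ms, the first bin
containing any suprathreshold sample, and the tests pin this convention.
Runs may complete anywhere within the epoch even if they start near the
500 ms search limit.

The threshold is baseline mean + 1 SD with both statistics *averaged
across trials*: each trial's baseline mean and SD over [-200, 0) ms are
computed after normalization and averaged. The alternative reading — mean
and SD over time of the trial-averaged baseline trace — is provided as
`baseline_stat = "average_trace"` but is not the default, because its SD
shrinks with the number of trials (roughly as 1/sqrt(n)): the threshold
then collapses onto the baseline mean and the detector fires on
single-trial noise runs, which destroyed planted-latency recovery and
shift-equivariance when we evaluated it. A fully per-trial threshold is
the third option.

A site's latency is the median over detected trials, invalid when fewer
than half the trials yield an onset. Gradient analysis correlates
(Spearman) latency and selectivity against the MNI y coordinate, with
region means for y < -45, [-45, -35] and > -35; the best-site-referenced
variant subtracts each subject's most human-face-selective site from both
axes, leaving within-subject ranks unchanged. Face-selective sites are
matched to task-active sites greedily by nearest y within 2 mm (one
task-active site may serve several face sites), followed by a paired
signed-rank test on the latencies; a matching with all-zero differences
reports p = 1 rather than a degenerate statistic.

## Stimulation statistics

The two-proportion z test is the classical pooled-variance form without
continuity correction; this choice reproduces the two reported
face-selective (6/17 vs 0/7, z = 1.815) and non-selective (3/14 vs 0/14,
z = 1.833) comparisons exactly at three decimals. The pooled comparison
printed alongside them (9/31 vs 0/21, printed z = 1.833) is *not*
reproduced by this formula (which gives ~2.72); since the variant behind
that single number is unknowable from the text, the package does not force
agreement and reports only the two comparisons it can reproduce. A
continuity-corrected variant sits behind a flag. Charge per trial is the
product pulse width (ms) x current (mA) x frequency (Hz) x duration (s),
in uC by the stated formula.

## Problem sizes and defaults

The demonstration pipeline (`run_pipeline()`) uses 12 synthetic sites —
eight face-responsive with selectivity falling and onset latency rising
anteriorly at 3 ms per mm, two responding to every category — and 10
images per category (20 trials per category, half the reference design)
with reduced permutation counts (2,000 activity / 1,000
selectivity / 100 decoding permutations; the reference values 50,000 /
10,000 / 1,000 are plain arguments away) and a fixed C = 1 without inner
search for the ensemble-scale models. Twenty trials per category is the
smallest design in which the paired activity test can clear FDR across a
dozen sites (the sign-flip null has at most `2^n` distinct values, so
10-trial designs cannot reach the corrected threshold) — test fixtures use
the same size for the same reason. The 499-model ensemble runs at 2-fold
cross-validation with fixed C, which keeps it under a minute on one CPU.

## Known limitations

* Planted dB amplitudes in the raw-signal path are attenuated by the
  pink-noise HFB floor; amplitude-accurate planting is only guaranteed by
  the band-power-level generator.
* The MKL optimizer is a projected-gradient scheme, not an exact solver;
  with strongly overlapping informative kernels the split of contributions
  among them is data- and path-dependent (the simplex constraint only
  fixes their sum).
* Absolute onset latencies depend on the bin convention and threshold;
  only latency *differences* and gradients are interpreted, and the
  detector is validated on exactly those.
* Serialization covers events/electrode tables (TSV) and results
  (JSON/TSV); raw-signal containers live as in-memory R objects.
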