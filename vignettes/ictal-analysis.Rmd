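---
title: "Methods: classifying and correlating cortical activity during spike-wave seizures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and correlating cortical activity during spike-wave seizures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictaltrace)
```

## The analytical problem

Absence seizures produce generalized 5–9 Hz spike-wave discharges (SWDs) on
the EEG with behavioral arrest. Two-photon calcium imaging during these
events asks three questions that this package operationalizes: does a given
neuron increase, decrease or hold its activity during seizures; how is its
engagement timed relative to electrographic onset and offset; and does the
apparently hypersynchronous EEG state correspond to synchrony among
individual neurons once the trivial effect of changed activity rates is
removed. Each question has a specific statistical trap — autocorrelated
fluorescence, seizure-locked nulls, and rate-dependent correlation bias —
and each stage below exists to avoid one of them.

## Seizure annotation

`detect_seizures()` automates printed criteria that, in practice, are often
applied by eye: candidate spikes are EEG peaks exceeding 1.5× the
background envelope, grouped into bursts at 5–9 Hz inter-spike intervals
(one missing spike may be bridged), with a minimum duration of 0.5 s and a
regularity requirement (inter-spike-interval coefficient of variation
≤ 0.25, which separates rhythmic discharges from chance chains of noise
peaks). "Background envelope" needs a quantitative definition: we use twice
the rolling MAD-derived sigma over 10 s — the ~95% amplitude band, which is
what a reader of EEG traces perceives as the background band — recomputed
once with detected bursts excluded. Onset and offset are the peaks of the
first and last spike. Burst edges are trimmed of candidate spikes below 60%
of the burst's median spike amplitude, which prevents chance noise peaks
just before onset or after offset from biasing the boundaries; on synthetic
sessions boundary error is below one EEG sample.

`filter_seizures()` applies the cross-contamination rules used before all
temporal analyses: calcium decays over hundreds of milliseconds, so
seizures shorter than 1.5 s, and seizures separated by less than 6 s, are
excluded (both members of a close pair). The 6-s rule is interpreted
offset-to-onset; since removal only widens surviving gaps, the operation is
idempotent. Frames are assigned to the ictal state when their midpoint
falls inside an accepted seizure; locomotion frames (|velocity| above
1 cm/s by default) can be excluded from both states.

## From fluorescence to ΔF/F

`compute_dff()` implements a percentile baseline: F(t) is the mean of the
bottom decile of samples within t ± 20 s (at least 4 samples; window
truncated at the edges), and ΔF/F = (x − F)/F, stored in percent. A 0.1 Hz
high-pass precedes baselining. We implement that high-pass as zero-phase
subtraction of a rolling bottom-quintile level over the cutoff period
(10 s) rather than as a linear filter, for two reasons discovered the hard
way. First, any linear high-pass has zero DC gain, so each positive
transient is balanced by shallow negative lobes spread over ~1/cutoff;
a percentile baseline computed afterwards rides those lobes instead of the
noise floor, smearing it severalfold. Second, any detrend that tracks the
local *mean* (or, at high transient occupancy, the median) subtracts more
during transient-rich periods than during suppressed ones — which
re-centres ictal and interictal segments onto a common level and erases
precisely the state contrast the classifier must measure. A low-percentile
level tracks the noise floor identically in both states, removing drift
without touching the contrast. The baseline is flagged degenerate (trace
excluded) if F(t) is ever non-positive or collapses below 1% of the trace
median.

`denoise_dff()` removes the noise floor with the half-Gaussian rule: the
peak (mode) of the trace distribution is located — under a bottom-decile
baseline the noise mode sits ~1.7σ above zero by construction, so the peak
must be estimated, not assumed at zero — and σ is the maximum-likelihood
half-Gaussian SD of the samples below the peak. Everything below
peak + 0.5σ becomes zero; for pure zero-mean noise this zeroes Φ(0.5) ≈ 69%
of samples and leaves a residual mean of φ(0.5)·σ ≈ 0.35σ. The mode is
located as the midpoint of the interval where a kernel density exceeds 80%
of its maximum, which is considerably more stable than the raw argmax.
Traces with fewer than 30 samples below the peak fall back to a robust
full-trace SD with a warning.

`flag_quiet()` excludes ROIs whose activity is too low to classify: summed
noise-corrected ΔF/F per minute below 6 for GCaMP6M or 22.5 for GCaMP6S.
The summation unit is fractional ΔF/F (not percent): at 10–20 Hz a typical
active neuron sums to tens of fractional units per minute against the
threshold of 6, reproducing quiet fractions around 10–15%, whereas in
percent units the same threshold would be three orders of magnitude below
any trace containing noise survivors and nothing would ever be quiet. This
unit choice is the package's resolution of an ambiguity in how the
thresholds are usually quoted.

## Ictal classification

`classify_roi()` compares all ictal with all interictal activity per ROI by
the two-sample Wilcoxon rank-sum test, Bonferroni-corrected across the
non-quiet ROIs of the session, with direction taken from the state means.
One numerical choice matters greatly: calcium traces are autocorrelated on
the indicator decay timescale (τ ≈ 0.6 s for GCaMP6M) and ictal frames
arrive in blocks, so a rank-sum over raw frames wildly understates its
variance — on planted-neutral populations we measured ~50% false positives
at a Bonferroni-corrected level. The states' frames are therefore
concatenated and binned at 1 s (≥ the decorrelation scale) before testing,
which restores the nominal false-positive rate (measured 0.25% per ROI at a
family of 200) while keeping ≥90% balanced recovery of planted suppressed
and activated neurons on a 30-minute, 60-neuron, 20-seizure reference
session. The sliding-window variant (`sliding_window_classes()`) uses 2-s
bins inside 7-minute windows advanced by one seizure; windows holding fewer
than two seizures are skipped, and per-neuron window-label fractions in the
predicted versus flipped class summarize stability.

## Seizure-aligned participation

`participation_profile()` aligns activity to onset (−10…+5 s) or offset
(−5…+10 s) in 30 bins of 0.5 s. The observed sample per bin holds one value
per seizure: the bin mean ΔF/F minus the ROI's overall mean (per-seizure
first, then tested — rather than pooled — so every seizure contributes
equally). The null preserves everything except seizure timing: each of the
2000 shuffles displaces all alignment points by one uniform circular offset
modulo the recording length, keeping seizure durations, their relative
spacing and the calcium trace intact, and the bin values are recomputed.
Each bin's observed sample is compared with its pooled null by a two-sample
Kolmogorov–Smirnov test at p < 0.05/30 ≈ 0.0017, and an ROI participates
when at least two adjacent bins are significant. Because the null is built
from the same trace, its autocorrelation structure is inherited exactly and
no binning correction is needed; on 200 planted-unmodulated ROIs the
participant rate is ≤1% and the per-bin rate sits at the nominal level.
Fewer than three seizures triggers a low-power warning rather than an
error. Bin values are evaluated through cumulative sums, so a full
2000-shuffle profile of a 60-ROI session costs seconds, not hours.

## Rate-corrected synchrony

`state_correlations()` resamples traces to 200-ms bins (a bin is used only
if all its frames share one state and none is excluded), normalizes each
ROI's ictal amplitude by its mean interictal amplitude, concatenates each
state's bins and computes Pearson coefficients per pair within ROI kind.
`shuffle_correct()` subtracts, per pair and state, the mean coefficient
over 2000 random circular shifts of one member's series. The per-offset
coefficients are obtained exactly for all offsets at once via FFT
cross-correlation and the seeded offsets index into that table — this is
numerically identical to shifting the series 2000 times at a fraction of
the cost. Offset zero is excluded; constant or sub-10-bin series are
skipped with a flag. On independent stationary pairs with a 5-fold rate
difference between states the mean corrected coefficient is zero to within
±0.02 in both states, which is the property the correction exists to
guarantee.

`rate_match_by_event_removal()` is the second, independent correction:
calcium events (maximal runs of consecutive nonzero denoised samples,
assigned to the state holding the majority of their frames) are deleted in
random order from the initially higher-rate state until the state means
agree within 0.1 percentage points. Deletion granularity sets a limit: when
single events move the ictal mean by more than the tolerance (short ictal
exposure), the best configuration is kept and the cell flagged unmatched.
Both corrections agree in the sign of the ictal-minus-interictal synchrony
difference on synthetic sessions.

## Deconvolution and patch-clamp analysis

`deconvolve_dff()` estimates event rates in two steps: iterative smoothing
(passes of 3-point median then 3-point mean until no local maximum of
prominence below 2σ remains, with samples rising >2σ above their smoothed
value *and* followed by another elevated sample — the signature of a
kernel-shaped transient, not a one-sample noise spike — kept unmodified),
then inverse filtering with the discrete exponential kernel:
rate(t) = x(t) − e^(−Δt/τ)·x(t−Δt), rectified at zero. τ defaults to 0.6 s
for GCaMP6M and 1.0 s for GCaMP6S. An exact exponential transient
deconvolves to a single nonzero sample, and the summed rate is linear in
transient amplitude. When inferred rates are re-classified for comparison
with the ΔF/F classification, they are first re-smoothed with a boxcar of
the kernel width (`smooth_rate_traces()`): deconvolution sharpens activity
to single frames, and comparing the two representations at matched temporal
resolution mirrors the standard practice of choosing the spike-rate
smoothing window that best matches deconvolved traces. With that matching,
the two classifications agree for >90% of ROIs.

`detect_aps()` applies three explicit criteria at every sample t (windows
in ms, thresholds in mV): (i) V(t+0.25) > V(t) + x; (ii) the pre-spike mean
over [t−pre₁, t−pre₂] lies below the peak mean over [t+p₁, t+p₂] minus
α·x; (iii) the post-spike mean over [t+post₁, t+post₂] lies below the
pre-spike mean plus β·x. Both published parameter sets are built in
(whole-cell x = 38 mV; cell-attached x = 1.9 mV) and window bounds round to
the nearest sample; runs of flagged samples within 1 ms collapse to the
earliest. Note that at 10 kHz the +0.25 ms offset of criterion (i) rounds
to +0.2 ms, so a waveform must complete its rise within 0.2 ms to be
scored at its nominal amplitude. `state_firing_rates()` compares per-seizure
ictal rates with flanking interictal rates by the paired signed-rank test;
`peri_eeg_spike_histogram()` references each AP to its nearest EEG spike
(ties to the earlier one), histograms offsets over ±100 ms in 20-ms bins,
reports the fraction of EEG spikes with an AP within ±20 ms, and tests
offset unimodality with the D'Agostino–Pearson omnibus statistic
(implemented from its standard definition, as no installed package provides
it).

## The synthetic-data generator

`simulate_session()` produces the study conditions every test and the
acceptance script run under. The EEG is pink (1/f) noise with planted SWD
bursts: biphasic sharp spikes (≈3 ms Gaussian core plus a slower negative
wave) at the configured 5–9 Hz rate, amplitude six times the background MAD
envelope, durations uniform on 2–8 s, bursts ≥8 s apart so they survive
curation. Calcium traces are inhomogeneous-Poisson event trains (interictal
rate 0.3 events/s jittered ±20% per neuron; planted-quiet neurons at
0.0005 events/s) whose rate is multiplied by (1 + depth) during seizures
(−0.8 for ictal-low, +1.5 for ictal-high, 0 for neutral), convolved with
exp(−t/0.6 s), scaled to 25% ΔF/F per event on a baseline of 100 with 0.5%
Gaussian noise and a slow ±2% multiplicative drift. Pairwise coupling uses
a shared latent train: a fraction f of every active neuron's events is the
same realization, planting event-level correlation f; the shared train is
thinned per neuron along with its modulation, so suppression also withdraws
a neuron from the common input (synchrony falls with activity, the
phenomenon of interest), and the shared state can be restricted to
interictal or ictal frames. Neuropil patches are means of ten random neuron
signals plus independent noise. Optional features: a modulation lead
(suppression beginning seconds before electrographic onset), Markov class
drift at epoch boundaries, locomotion bouts placed away from seizures, and
10-kHz voltage traces with stereotyped spikes satisfying the detection
criteria of their mode.

The free generator constants were fixed once, jointly, so that the printed
pipeline is self-consistent: with 0.5% noise the GCaMP6M quiet threshold of
6 fractional units/min cleanly separates pure-noise ROIs (residual
≈ 5.4σ/min ≈ 2.7) from active ones (≳ 25), and 25% events at 0.3 events/s
give the rank-sum full power at 20 seizures. What the generator does *not*
emulate: sub-Poisson spiking statistics, indicator nonlinearity and
saturation, neuropil contamination of somatic ROIs, motion artifacts, slow
z-drift, or inhomogeneous noise across the field. Passing recovery tests on
this generator therefore demonstrates the statistical machinery, not
robustness to those real-data pathologies.

## Numerical choices and limitations

* Sliding windows anchor at the recording start; each successive window
  starts just after the previous window's earliest seizure onset, dropping
  exactly that seizure.
* The Bonferroni family for classification is the session's non-quiet ROI
  count; the participation family is the 30 bins.
* Circular shifts in the synchrony null exclude offset zero and are applied
  within each state's concatenated series independently.
* Ties in rank-sum and KS tests are handled by the normal approximation;
  the heavy zero-inflation of denoised traces makes exact p-values
  unavailable anyway.
* Determinism: a single seed controls every stochastic stage through
  stage-name-keyed substreams; rerunning a pipeline with the same seed
  reproduces every table bit for bit.
* Test problem sizes: unit tests use 2–10-minute sessions with 8–30 ROIs;
  the acceptance checks use a 30-minute 60-neuron reference session, a
  20-minute 200-ROI null-calibration session and 1000-shuffle corrections,
  which keeps the full suite within a coffee break on one CPU.
* Known limitations: the seizure detector is a stand-in for expert
  annotation and has only been validated on synthetic EEG (annotations can
  be supplied externally and passed straight to `filter_seizures()`);
  kernel bleed at state transitions inflates ictal correlations of
  strongly modulated pairs, which is physical but means corrected ictal
  coefficients on real data retain transition structure; and the
  expectation-maximization style of spike inference is out of scope — the
  exponential-kernel inverse filter is the only deconvolution shipped.
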