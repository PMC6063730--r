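---
title: "State-dependent membrane potential and unitary EPSP analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-dependent membrane potential and unitary EPSP analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statephys)
```

## The scientific problem

Awake cortex alternates between a *quiet* regime — no whisker movement,
large 1–5 Hz ("delta") fluctuations in the local field potential (LFP) —
and an *active* regime in which the animal whisks and low-frequency LFP
power collapses. Inhibitory interneuron classes respond differently to this
switch: parvalbumin-expressing (PV) cells depolarize during active states
while somatostatin-expressing (Sst) cells hyperpolarize, and both reduce
their firing rates. A candidate mechanism is a state-dependent change in
the efficacy of local excitatory synapses, measurable as the amplitude of
unitary excitatory postsynaptic potentials (uEPSPs) evoked by
optogenetically driving a single presynaptic pyramidal neuron at 1 Hz.

`statephys` implements the full analysis chain needed to ask these
questions of a recording session — state segmentation, state-resolved
membrane potential (Vm) statistics, triggered-average uEPSP
quantification, and exact nonparametric tests — together with a synthetic
session generator that plants known ground truth, so every stage can be
validated end to end.

## State segmentation

**Whisking (W / NW).** Whisker speed is `|d(angle)/dt|` of the 200 Hz
whisker-angle trace, smoothed with a 25 ms boxcar. Samples with speed
strictly above a threshold (default 50 °/s) form W epochs. The threshold is
a free parameter: the original video-based routines do not prescribe a
value, so it is configurable and all synthetic validation uses bout speeds
far above it (a 20°, 8 Hz bout peaks above 1000 °/s). NW is the complement
after trimming a 50 ms transition buffer around each W epoch; both sets
then get a gap-merge (0.1 s) and minimum-epoch (0.2 s) cleanup, so part of
the recording may remain unassigned. A speed exactly at threshold counts
as NW (strict inequality).

**LFP power (L / H).** The LFP is decimated to 2000 Hz, low-pass filtered
at 200 Hz with a zero-phase (forward–reverse) 4th-order Butterworth
filter, and scanned with a sliding rectangular 2 s FFT window advanced by
10 ms. Band power is the sum of squared DFT magnitudes over the bins with
frequencies in [1, 5] Hz inclusive (0.5 Hz bin spacing). Each window's
power is attributed to its center time, so the first and last second of a
recording are uncovered. Thresholds are the 40th and 60th percentiles
(linear interpolation) of the pooled per-recording power distribution:
windows strictly below the 40th percentile are L, strictly above the 60th
are H, and the middle quintile stays unassigned — with all-equal power
values both sets are empty. By construction at most 40% of windows land in
each extreme.

**Quiet / Active.** Active = W ∩ L, Quiet = NW ∩ H, intersections taken on
half-open intervals; the discordant combinations (W ∩ H, NW ∩ L) are left
unassigned. A stimulus belongs to a state only when the window from 20 ms
before to 30 ms after its onset lies continuously inside that state; a
window exactly coinciding with an interval's span is accepted (half-open
boundary rule).

## State-resolved Vm statistics

Spike peaks are detected from the rate of rise (default 20 V/s) with a
2 ms refractory period and a minimum-peak criterion. Mean and population
SD of Vm pool all samples inside a state's intervals after excising
−1/+4 ms around every spike peak and the 50 ms following every optogenetic
pulse, so the statistics describe spontaneous activity; the excision
windows are configurable because the underlying experimental convention
specifies only that spikes are excluded. When nothing survives, the result
is flagged undefined rather than reported as zero.

Spectra use non-overlapping 1 s segments placed greedily from the start of
each state interval. The Vm is median-filtered (8 ms default) to remove
spikes; each segment's single-sided FFT amplitude `2|X(f)|/N` (DC
excluded) is averaged across segments, and the 1–5 Hz band amplitude is
the mean over the five 1 Hz-resolution bins at 1–5 Hz. A 4 Hz tone of
5 mV therefore reads 5 mV at its bin and 1 mV as the band mean.

For the Vm–LFP cross-correlation both signals are brought to 2000 Hz (the
LFP additionally low-pass filtered at 200 Hz), and each 1 s segment of
*both* signals is mean-subtracted and normalized by its population SD.
Normalizing both series — rather than the Vm only — makes the result a
bounded, Pearson-style coefficient comparable across cells; this is a
deliberate design choice, and it guarantees |r| ≤ 1. The per-segment
correlations are averaged over lags within ±0.1 s and the peak is the
extremum of largest absolute value, reported with its sign and lag
(positive lag = LFP lags Vm). Zero-variance segments are skipped.

## uEPSP quantification

A presynaptic AP counts as optogenetically evoked when its peak falls
within 10 ms after light onset; latency is stimulus-to-peak time and
jitter its SD. For the postsynaptic average, stimuli are dropped when any
postsynaptic spike peak falls in the 50 ms window starting 20 ms before
the pulse, and the remaining −20/+50 ms segments are averaged and smoothed
(0.5 ms boxcar). Quantification operates on the averaged waveform, not on
single trials: the smoothed first derivative must exceed 100 mV/s (PV) or
60 mV/s (Sst) within 30 ms of the pulse to define the onset; the peak is
the first subsequent zero crossing of the derivative; amplitude is the
difference between 0.25 ms means centered at the peak and immediately
before the onset; the 20–80% rise time is obtained by linear interpolation
on the rising phase. The smoothing kernels (0.5 ms waveform, 1.0 ms
derivative) are free choices — no kernel is prescribed by the convention
being implemented — and are configurable. Centered smoothing biases the
detected onset earlier by roughly half the derivative-smoothing span
(~0.5–0.75 ms at the defaults); amplitude is essentially unaffected
because it is measured between windows several milliseconds apart. If the
derivative never crosses threshold, the result is "no uEPSP detected" with
an undefined, not zero, amplitude.

Paired Active-minus-Quiet contrasts are tested one-tailed in the
hypothesized direction — amplitude increase and baseline depolarization
for PV, the reverse for Sst — with the exact signed-rank test below.

## Exact nonparametric tests

Zero differences are dropped (standard Wilcoxon convention); tied
magnitudes get mid-ranks. For n ≤ 25 the null distribution of the
signed-rank statistic W⁺ is computed exactly over all 2ⁿ sign assignments
via the generating-polynomial convolution over doubled ranks (identical to
literal enumeration, which the test suite performs independently at
n ≤ 10). One-tailed p = P(W⁺ ≥ w) for direction "greater"; two-tailed
p = 2·min(tail p's), capped at 1. Five concordant pairs give
p = 1/32 ≈ 0.031. The rank-sum test enumerates all C(n₁+n₂, n₁) group
assignments the same way. Beyond n = 25 both tests fall back to a normal
approximation with continuity and tie corrections and are flagged
`exact = FALSE`. Box summaries use interpolated quartiles with whiskers at
the extreme data points within 1.5 IQR of the quartiles.

## The synthetic generator

`generate_session()` plants a two-state semi-Markov alternation with
exponential dwell times (mean 8 s) truncated below at 1 s so that 2 s FFT
windows fit inside epochs. The LFP delta component is amplitude-modulated
1–5 Hz narrowband noise — filtered white noise rescaled to unit RMS, not a
pure sinusoid — so the percentile classifier faces a realistic power
distribution; a pure-tone mode exists for analytic tests. Default RMS
amplitudes are 0.5 mV (quiet) and 0.125 mV (active). The whisker is
stationary outside active epochs and carries a tapered 20°, 8 Hz sinusoid
inside them, so whisking and low LFP power coincide by default; a
`disagreement_fraction` can decouple them to exercise the unassigned
categories.

The subthreshold Vm is rest (−60 mV) + a signed active-state shift
(+3 mV PV-like, −3 mV Sst-like) + a coupling gain times the LFP delta
component (6 for PV-like, 0.3 for Sst-like) + band-limited noise (0.5 mV
SD, 100 Hz). uEPSPs are difference-of-exponential kernels (0.5/5 ms)
normalized to unit peak and scaled by the planted per-state amplitude,
each following a presynaptic juxtacellular AP (2.5 ± 0.3 ms after each
1 Hz light pulse) at a 1.5 ms synaptic delay. Spikes are stylized 2 ms
templates reaching 60 mV above threshold, injected at threshold crossings
of the subthreshold Vm with a 5 ms refractory period. The thresholds
(−53.5 mV PV-like, −58.75 mV Sst-like) were placed once so that quiet-state
firing sits at a realistic few Hz and collapses in the active state: PV
quiet firing is driven by the large delta-coupled fluctuations, which
vanish in the active state faster than the depolarization closes the gap
to threshold — reproducing the depolarized-yet-quieter active PV
phenotype. Cohorts jitter resting Vm (±1 mV SD, with the spike threshold
shifted alongside so the operating point is preserved), the state shift
(±0.5 mV SD) and a shared log-normal uEPSP amplitude factor (CV 0.1) per
cell, with per-cell seeds derived deterministically from the master seed.

What the generator does **not** emulate: conductance-based spike dynamics,
synaptic short-term plasticity, movement artifacts, electrode drift,
recording-quality variation, or the heavy-tailed epoch-duration and power
distributions of real recordings. Passing the recovery tests therefore
demonstrates the correctness of the analysis chain under the assumed
statistical structure, not fidelity to any particular real dataset.

## Numerical choices and degenerate inputs

Intervals are half-open `[start, end)` in seconds; all cross-rate
alignment happens in seconds, never sample indices, with a quarter-sample
epsilon guard where window edges meet sample times. Decimation takes every
k-th sample and requires an integer factor. The sliding-window DFT is
evaluated exactly (block matrix products against the in-band complex
exponentials), which matches a per-window FFT oracle to ~1e-12 relative.
Degenerate inputs are handled explicitly: empty states, zero-variance
cross-correlation segments, all-zero difference vectors (p = 1,
degenerate flag), all-equal power distributions (no L/H assignment), and
whisker traces shorter than the minimum epoch (empty sets with a warning).

## Problem sizes used in validation

The test suite validates the classifier on twenty 20-minute synthetic
sessions (LFP and whisker channels, 4× planted power contrast), uEPSP
recovery on ten 6-minute fully-stimulated sessions (≥ 40 eligible stimuli
per state, 0.3 mV noise), and the class-specific direction of effect on
twenty cohorts of 5 PV-like plus 5 Sst-like 60 s sessions analyzed from
raw traces; these sizes were chosen as the smallest at which the planted
effects dominate sampling variability by a comfortable margin. Unit tests
use seconds-long fixtures built in code.

## Known limitations

* The whisker-speed threshold and epoch-cleanup constants are conventions,
  not fitted quantities; real recordings may need tuning.
* The onset-latency estimate inherits the early bias of centered
  smoothing described above.
* Exact tests switch to a normal approximation beyond n = 25.
* `read_session()` expects the package's own directory layout; acquisition
  formats (e.g. IgorPro binaries) are out of scope.
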