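---
title: "Quantifying environmental-memory responses in LIP spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying environmental-memory responses in LIP spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipmemory)
```

## The measurement problem

A parietal neuron can respond after a saccade brings the remembered
location of a vanished stimulus into its receptive field, even though
nothing is on the screen there. Quantifying this *environmental memory*
response from blocked task recordings requires answering four questions
per cell — is postsaccadic activity on probe-absent memory trials
elevated over the baseline block? by how much? with what onset latency?
and how fast does it fade once the probe stops appearing? — and then two
at the population level: what fraction of cells carry the effect, and is
the population's memory-index distribution shifted and skewed toward
memory rather than being the upper tail of a symmetric distribution?

All analyses align spikes to saccade onset (t = 0, times in ms;
presaccadic times negative). The data model is deliberately minimal: a
`CellRecording` holds one unit's trials as an events table (block,
condition, saccade identity, fixation onset, optional probe onset, trial
end) plus one spike-time vector per trial. Two task layouts are
supported: the *basic* task (baseline / 100%-probe / mixed
probe-present-and-absent / forgetting, blocks 1–4) and the *no-RF* task,
in which the probe never stimulates the receptive field before the
memory is probed (baseline / mixed with a different saccade on
probe-present trials / forgetting / visual-control). The on-disk format
is a two-table CSV pair (events, spikes) so that zero-spike trials
survive round trips.

## PSTHs and response metrics

PSTHs use 2-ms half-open bins, averaged across trials; the rate in
spikes/s integrates back to the mean per-trial spike count over any bin
span (mass conservation), which the tests assert. Smoothing is a 10-ms
*causal* filter, implemented as a trailing boxcar (the current bin plus
the four preceding 2-ms bins); bins too early for a full history average
over the available prefix, so constants are preserved and output length
equals input length. The filter shape is not dictated by the measurement
model beyond causality — the trailing boxcar is the simplest filter
matching it, and per-bin SEMs are recomputed from per-trial smoothed
rates. Baseline normalization divides by the block-1 baseline-window
mean rate, so baseline activity reads as 1 and responses as
fold-changes; subtraction and no-op modes are available
(`normalizationMode` in `analysisConfig()`), and normalization commutes
with smoothing.

Scalar metrics live in fixed windows chosen once (`analysisWindows()`):

| quantity | definition | default |
|---|---|---|
| baseline | median per-trial count, presaccadic window | [−426, −226) ms |
| peak time | argmax of smoothed PSTH, earliest tie | search [−125, +500] ms |
| amplitude | median per-trial *raw* count around peak | peak ± 100 ms |

The peak search extends 125 ms before the saccade so that predictive
remapping responses are not missed. Amplitude quantification uses raw,
unsmoothed counts; smoothing only locates the peak. For the memory
index, (R_mem − R_pre)/(R_mem + R_pre), the quantification window is
located once on the memory-condition PSTH and then applied identically
to the baseline-block trials: refitting the window per condition would
bias R_pre downward through selection, while a shared window compares
like with like. The same shared-window counts feed the per-cell
classification (two-sided Wilcoxon rank sum at α = 0.05, plus the
directional requirement that median memory activity exceed baseline —
without the direction filter a two-sided test would also flag
suppression, which is not a memory response).

Cells whose block-1 activity differs between the presaccadic baseline
window and a postsaccadic window are excluded: apparent "memory"
activity in such a unit could be eye-position or saccade modulation.
The postsaccadic window is not dictated by the design; [+50, +250) ms
was chosen to mirror the 200-ms baseline duration while skipping the
perisaccadic transient, and it is configurable.

## Onset latency: two estimators

**Median threshold crossing.** Baseline firing drifts, so the reference
window is selected adaptively: 200-ms subwindows slide in 1-ms steps
through [fixation, −226] ms; each window's median per-trial count is
computed, and the window matching the median of those medians (within
one spike) with the *latest* start — closest to the response epoch —
wins, deterministically. The cutoff is the 75th percentile of the
per-bin detection statistic inside that window, and the latency is the
first bin of the first run of at least 5 consecutive 2-ms bins strictly
above the cutoff (ties do not cross; a 20-ms/10-bin criterion is
available via `sustainedBins`).

The detection statistic needs care. The across-trial *median* of raw
2-ms bin counts is degenerate at typical cortical rates: a bin's median
is nonzero only when more than half the trials spike inside the same
2 ms, i.e. at ⪆350 spikes/s. Each trial is therefore integrated over
the 50 ms *preceding* each bin edge (a causal window, matching the
rank-sum method's width) before the median is taken. This keeps the
median informative at ordinary rates, retains 2-ms resolution, and —
because the integration window never sees spikes after its bin — the
estimated latency cannot precede a true onset by more than one bin. On
simulated 300-trial step responses (10 Hz baseline, +50 Hz at +100 ms)
the estimator lands in [101, 105] ms essentially always, and flat cells
yield no latency.

**Sliding rank-sum fallback.** Responses that build gradually, or that
are carried by a subset of trials, defeat a sustained median crossing.
For these, 50-ms windows slide in 1-ms steps through the response
epoch; each window's per-trial counts are compared against baseline
counts by a two-sided rank sum, and the latency is the start of the
first run of ≥ 20 consecutive significant positions. Two numerical
choices matter here. First, the baseline sample is the pooled per-trial
counts of the four disjoint 50-ms quarters of the selected baseline
window: comparing 50-ms counts against 200-ms counts rescaled to rates
leaves a dispersion mismatch that a rank test detects spuriously at
large trial counts, whereas equal-duration counts are identically
distributed under stationary firing. Second, because these windows
extend *forward*, the estimate can precede a sharp onset by up to the
window width; the two estimators therefore bracket a step onset from
opposite sides, which the tests assert. `estimateLatency()` tries the
threshold method first and reports which method produced the estimate.

At a few tens of trials per condition both estimators are noisy — the
across-trial median statistic sits near its flip point at a 10 Hz
baseline, producing occasional spurious early runs. Per-cell latencies
at that scale should be read as distributions, not point estimates;
population comparisons (memory vs visual latency) remain reliable when
averaged over enough cells, and the validation suite powers that
comparison with 100-cell populations given the ~70 ms per-cell spread.

## Population statistics

The memory-index distribution is summarized by its median, the
medcouple, and a median-shift test. The medcouple is the median of the
kernel h(x_i, x_j) = ((x_j − m) − (m − x_i))/(x_j − x_i) over all pairs
with x_i ≤ m ≤ x_j (m the sample median), with the standard −1/0/+1
anti-diagonal kernel for pairs tied at the median; it is bounded in
[−1, 1], invariant under positive affine maps, antisymmetric under
negation, and insensitive to tail magnitude. Evaluation is the naive
exhaustive O(n²) pass — populations here are tens to hundreds of cells,
where this costs microseconds — and the tests pin it pairwise against an
independently coded oracle.

The median-shift test pairs the sample with a copy of itself recentered
by its own mean and applies a signed-rank test. As specified, every
paired difference equals the sample mean, so the statistic carries no
information beyond the sign of the mean and the sample size: the test
degenerates to an exact sign decision with two-sided p = 2^−(n−1) for a
non-zero mean (computed exactly from the tied-rank enumeration rather
than a normal approximation) and p = 1 for a mean of exactly zero. The
implementation is faithful to that definition and the degeneracy is
stated rather than hidden; the medcouple and the index median are the
informative complements.

## Forgetting decay

Per-trial activity in the cell's memory quantification window is tracked
through the first 50 trials of the forgetting block (blocks can run
longer; the analysis epoch is capped at 50). Three normalizations are
implemented because each answers a slightly different control question:
the mean of the last five probe-present trials (default — anchors decay
to the immediately preceding established response), the cell's peak
memory activity, and the mean over the whole probe-present block
(controls for fast build-up and between-block fluctuations). The
population trace is the across-cell mean of the normalized series, fit
by least squares to y(n) = a·e^(−k·n) + c with k ≥ 0. The offset c is
included because population traces do not decay to zero. The fit uses
Levenberg–Marquardt from a fixed grid of starting rates (0.01–1 per
trial), choosing the best start by residual sum of squares, so it is
deterministic; a constant series returns the degenerate k = 0 fit. R²
may legitimately be negative when the trace decays more slowly than any
exponential with this form fits. Both k (per trial) and τ = 1/k
(trials) are reported. Early-versus-late change is tested by a
two-sample rank comparison of the first and last 10 trials within the
50-trial epoch — two-sample rather than paired, since the trials are
independent draws, not matched pairs.

## The synthetic generator

`generateCell()` draws every trial from an inhomogeneous Poisson process
(thinning algorithm) whose rate is the sum of a tonic baseline, a visual
boxcar on trials where the saccade brings the probe into the receptive
field, a memory boxcar on probe-absent memory and forgetting trials —
its amplitude decaying as e^(−k·ordinal) through the forgetting block —
and an optional postsaccadic eye-position term used to exercise the
exclusion test. Defaults describe a typical memory cell: 10 Hz baseline;
visual response +40 Hz at 36 ms lasting 150 ms; memory response +20 Hz
at 100 ms lasting 200 ms (weaker and later than the visual response, as
observed); decay k = 0.3 per trial; block sizes 20/30/60/100 with the
mixed block interleaving probe-present and probe-absent trials half and
half; fixation at −1200 ms so the baseline machinery always has room;
trials end at +800 ms, covering the +500 ms peak search plus the +100 ms
quantification margin. In the no-RF layout, probe-present mixed-block
trials use the alternative saccade and thus produce *no* visual
response, matching the task's logic of establishing a memory without
retinal stimulation.

Boxcar profiles expose exactly the features the analysis measures —
onset, amplitude, duration — and nothing else. The generator does *not*
emulate gamma-shaped transients, bursting or non-Poisson count
dispersion, latency jitter across trials, slow excitability drifts, or
eye-movement traces. Passing recovery tests therefore demonstrates that
the estimators are correct for piecewise-stationary Poisson firing, not
that they are robust to every property of real recordings; the
overdispersion of real spike counts will widen all sampling
distributions.

## Validation at a glance

The test suite regenerates every fixture in code. Problem sizes were
chosen to make each check sharp while keeping the suite fast: exact
algebraic anchors for the index and medcouple (500 random samples up to
n = 50 against the exhaustive oracle); 100 seeded 300-trial step cells
for latency recovery into [100, 112] ms with matched flat-cell
controls; 20 seeded 50-cell populations per decay rate k ∈ {0.05, 0.1,
0.3}, scored at the replicate median against ±30%; 200 null and 200
strong-memory cells for the classification error rates; three seeded
100-cell populations for the weaker/later memory-signature ordering;
and byte-level determinism of the simulate-analyze round trip.

## Limitations

Per-cell latency at tens of trials is noisy (see above); the rank-sum
run rule admits occasional false runs on long stationary epochs because
overlapping windows are heavily autocorrelated; the median-shift test is
informative only about the sign of the mean by construction; decay fits
on single cells are unstable and only the population fit is reported as
an estimate; and the CSV reader targets this package's two-table layout,
not general electrophysiology containers.
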