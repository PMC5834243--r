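# lipmemory

Quantification of *environmental memory* responses in saccade-aligned
single-unit spike trains.

Neurons in the lateral intraparietal area (LIP) can fire after a saccade
brings the spatial location of a previously shown — but now absent —
stimulus into their receptive field. This postsaccadic "memory of the
environment" is typically weaker and later than the same neuron's visual
response, and it fades over trials once the stimulus stops appearing.
`lipmemory` implements the full quantification pipeline for blocked
memory-task recordings of this kind, for electrophysiologists analyzing
trial-aligned spike data: peristimulus time histograms, response-window
metrics, onset latencies, memory-cell classification, population
distribution statistics, and forgetting-decay fits. A seeded
inhomogeneous-Poisson simulator generates recordings with the same task
structure, so every stage is testable end to end and parameter recovery
can be scored against ground truth.

## The quantities at its core

With all times aligned to saccade onset (t = 0):

- **PSTH** — 2-ms spike bins averaged across trials, smoothed with a
  10-ms sliding causal (trailing boxcar) filter, optionally normalized to
  block-1 baseline activity.
- **Response metrics** — baseline activity is the median per-trial spike
  count in the presaccadic window [−426, −226) ms; peak activity is
  located on the smoothed PSTH in [−125, +500] ms (extended before the
  saccade to capture predictive remapping) and quantified as the median
  raw spike count in the ±100 ms window around the peak.
- **Memory index** — with R_mem the postsaccadic activity on probe-absent
  memory trials and R_pre the matched baseline-block activity, both in
  the same quantification window:

      index = (R_mem − R_pre) / (R_mem + R_pre)  ∈  [−1, 1]

- **Onset latency** — a median threshold-crossing and sustained-response
  method (75th-percentile cutoff from an adaptively selected 200-ms
  baseline subwindow; first run of ≥ 5 consecutive 2-ms bins above the
  cutoff), with a sliding 50-ms Wilcoxon rank-sum scan as fallback for
  gradually building responses.
- **Memory-cell classification** — per-trial rank-sum comparison of
  block-1 versus probe-absent memory-trial activity (α = 0.05, with the
  requirement that memory exceed baseline), plus an eye-position
  exclusion test comparing pre- and postsaccadic block-1 activity.
- **Population statistics** — the memory-index distribution is summarized
  by its median, a mean-recentered signed-rank shift test, and the
  **medcouple**, a robust skewness statistic in [−1, 1].
- **Forgetting decay** — per-trial memory-window activity through the
  first 50 trials of the forgetting block, normalized (by default) to the
  mean of the last five probe-present trials, averaged across cells and
  fit with a first-order exponential `y = a·exp(−k·n) + c`, `k ≥ 0`,
  plus a rank comparison of the first and last 10 trials.

## Worked example

```r
library(lipmemory)

cell <- generateCell(syntheticCellParams(seed = 7),
                     cellId = "u042", monkeyId = "A")
cell
#> CellRecording 'u042' (monkey A, basic task)
#>   210 trials, 4718 spikes total
#>   trials per block: 1:20  2:30  3:60  4:100

cls <- classifyMemoryCell(cell)
cls$window                       # memory quantification window (ms)
#> [1]  75 275
c(cls$rMem, cls$rPre, cls$memoryP)
#> [1] 5.00e+00 2.00e+00 1.15e-06
memoryIndex(cls$rMem, cls$rPre)$index
#> [1] 0.4285714

estimateLatency(trialsWhere(cell, condition = "probe_absent_memory"))
#> $latencyMs [1] 53      $method [1] "threshold_crossing"

fitExponential(buildDecaySeries(cell))[c("k", "tau", "rSquared")]
#> $k [1] 0.1149...   $tau [1] 8.7      $rSquared [1] 0.06
```

The cell responds about 2.5× more strongly on memory trials than on
matched baseline trials (median 5 vs 2 spikes in the ±100 ms peak
window, rank-sum p ≈ 1e−6, index 0.43), and its memory activity decays
across forgetting trials with rate constant k ≈ 0.11 per trial. Note the
low R² — single-cell decay series are noisy, which is why the
population-level fit (`populationDecay()`) is the primary decay
estimate. Whole populations run through `generatePopulation()`,
`analyzeDataset()` (per-cell summary, population summary and decay CSVs)
and `recoveryReport()` for scoring against simulation ground truth.

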