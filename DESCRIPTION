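Package: lipmemory
Title: Quantification of Environmental-Memory Responses in Saccade-Aligned Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying postsaccadic "environmental memory" responses
    in single-unit extracellular recordings from parietal cortex. Provides
    saccade-aligned peristimulus time histograms with causal smoothing and
    baseline normalization, window-based response metrics (baseline, peak,
    memory index), onset-latency estimation by median threshold crossing and
    sliding rank-sum tests, memory-cell classification with eye-position
    exclusion, population skewness statistics (medcouple), exponential
    forgetting-decay fits, and a seeded inhomogeneous-Poisson spike-train
    simulator that reproduces the blocked task structure for validation and
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
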