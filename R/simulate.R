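#' Parameters for a synthetic unit
#'
#' Defaults describe a typical memory cell: a moderate tonic baseline, a
#' short-latency high-amplitude visual transient (mean visual latency in
#' the recordings is a few tens of ms), and a weaker, later memory response
#' (longer latency, lower amplitude than the visual response) that decays
#' exponentially across forgetting trials. Response profiles are boxcars —
#' the simplest shape exposing the onset latency and amplitude that the
#' analysis measures.
#'
#' @param baselineRateHz tonic firing rate (spikes/s).
#' @param visualAmpHz visual response amplitude above baseline (spikes/s).
#' @param visualLatencyMs visual onset latency after the saccade (ms).
#' @param visualDurationMs visual response duration (ms).
#' @param memoryAmpHz memory response amplitude (spikes/s); 0 for a
#'   no-memory cell.
#' @param memoryLatencyMs memory onset latency (ms).
#' @param memoryDurationMs memory response duration (ms).
#' @param decayKPerTrial forgetting-decay rate constant (per trial).
#' @param nBlockTrials per-block trial counts in block order (basic task
#'   default 20/30/60/100; the mixed block interleaves probe-present and
#'   probe-absent trials half and half).
#' @param task \code{"basic"} or \code{"no_rf"}.
#' @param eyePositionModulationHz tonic postsaccadic rate increment present
#'   in every trial of every block (default 0); used to exercise the
#'   eye-position exclusion test.
#' @param fixationOnMs fixation onset (ms; default -1200 so the baseline
#'   scan machinery always has room).
#' @param trialEndMs end of the recorded trial (ms; default +800).
#' @param probeOnMs probe onset on probe-present trials (ms; default -500,
#'   before the saccade that brings its location into the receptive field).
#' @param seed integer master seed; every spike train is reproducible
#'   from it.
#' @return a list with class \code{"SyntheticCellParams"}.
#' @export
syntheticCellParams <- function(baselineRateHz = 10, visualAmpHz = 40,
                                visualLatencyMs = 36, visualDurationMs = 150,
                                memoryAmpHz = 20, memoryLatencyMs = 100,
                                memoryDurationMs = 200,
                                decayKPerTrial = 0.3,
                                nBlockTrials = NULL, task = "basic",
                                eyePositionModulationHz = 0,
                                fixationOnMs = -1200, trialEndMs = 800,
                                probeOnMs = -500, seed = 1L) {
  task <- match.arg(task, .TASKS)
  if (is.null(nBlockTrials))
    nBlockTrials <- if (task == "basic") c(20L, 30L, 60L, 100L)
                    else c(20L, 60L, 100L, 30L)
  stopifnot(baselineRateHz >= 0, visualAmpHz >= 0, memoryAmpHz >= 0,
            visualLatencyMs > 0, visualLatencyMs < 500,
            memoryLatencyMs > 0, memoryLatencyMs < 500,
            visualDurationMs > 0, memoryDurationMs > 0,
            decayKPerTrial >= 0, eyePositionModulationHz >= 0,
            length(nBlockTrials) == 4L, all(nBlockTrials >= 1L),
            fixationOnMs < -426, trialEndMs > 0)
  structure(list(
    baselineRateHz = baselineRateHz, visualAmpHz = visualAmpHz,
    visualLatencyMs = visualLatencyMs, visualDurationMs = visualDurationMs,
    memoryAmpHz = memoryAmpHz, memoryLatencyMs = memoryLatencyMs,
    memoryDurationMs = memoryDurationMs, decayKPerTrial = decayKPerTrial,
    nBlockTrials = as.integer(nBlockTrials), task = task,
    eyePositionModulationHz = eyePositionModulationHz,
    fixationOnMs = fixationOnMs, trialEndMs = trialEndMs,
    probeOnMs = probeOnMs, seed = as.integer(seed)),
    class = "SyntheticCellParams")
}

## piecewise-constant trial rate (spikes/s) at times t (ms)
.trialRateFun <- function(p, condition, saccadeId, forgetOrdinal) {
  visual <- condition %in% .PROBE_CONDITIONS && saccadeId == "s1"
  memory <- condition %in% c("probe_absent_memory", "forget")
  memAmp <- if (!memory) 0 else if (condition == "forget")
    p$memoryAmpHz * exp(-p$decayKPerTrial * forgetOrdinal) else p$memoryAmpHz
  function(t) {
    r <- rep(p$baselineRateHz, length(t))
    if (visual)
      r <- r + p$visualAmpHz * (t >= p$visualLatencyMs &
                                t < p$visualLatencyMs + p$visualDurationMs)
    if (memory && memAmp > 0)
      r <- r + memAmp * (t >= p$memoryLatencyMs &
                         t < p$memoryLatencyMs + p$memoryDurationMs)
    if (p$eyePositionModulationHz > 0)
      r <- r + p$eyePositionModulationHz * (t >= 0)
    r
  }
}

## inhomogeneous Poisson spike train on [t0, t1] ms by thinning
.thinPoisson <- function(rateFun, rateMax, t0, t1) {
  if (rateMax <= 0) return(numeric(0))
  durS <- (t1 - t0) / 1000
  n <- stats::rpois(1, rateMax * durS)
  if (n == 0L) return(numeric(0))
  cand <- sort(stats::runif(n, t0, t1))
  keep <- stats::runif(n) < rateFun(cand) / rateMax
  cand[keep]
}

#' Generate one synthetic unit
#'
#' Simulates every trial of one blocked task session as an inhomogeneous
#' Poisson process (thinning algorithm) whose rate is the sum of the tonic
#' baseline, a visual boxcar on trials in which the saccade brings the
#' probe into the receptive field, a memory boxcar on probe-absent memory
#' and forgetting trials — with amplitude decaying as
#' \code{exp(-decayK * ordinal)} through the forgetting block — and an
#' optional postsaccadic eye-position modulation. Mixed-block trial types
#' are interleaved pseudorandomly (half probe-present, half probe-absent).
#' One RNG substream per trial is derived from the master seed, so the
#' whole recording is reproducible from \code{params$seed}.
#'
#' @param params a [syntheticCellParams()] list.
#' @param cellId,monkeyId identifiers for the generated recording.
#' @return a validated \linkS4class{CellRecording}.
#' @examples
#' cell <- generateCell(syntheticCellParams(seed = 7))
#' cell
#' @export
generateCell <- function(params = syntheticCellParams(), cellId = "sim1",
                         monkeyId = "simA") {
  p <- params
  layout <- .LAYOUT[[p$task]]
  sacc <- .SACCADE_LAYOUT[[p$task]]
  blockConds <- lapply(sort(unique(unname(layout))), function(b)
    names(layout)[layout == b])

  conditions <- character(0)
  withr_seed <- p$seed %% 2147483646L + 1L
  set.seed(withr_seed)
  for (b in seq_along(blockConds)) {
    conds <- blockConds[[b]]
    nb <- p$nBlockTrials[b]
    if (length(conds) == 1L) {
      conditions <- c(conditions, rep(conds, nb))
    } else {
      ## mixed block: half probe-present, half probe-absent, interleaved
      nPresent <- floor(nb / 2)
      mix <- c(rep("probe_present_mixed", nPresent),
               rep("probe_absent_memory", nb - nPresent))
      conditions <- c(conditions, sample(mix))
    }
  }
  nTotal <- length(conditions)
  trialSeeds <- sample.int(2147483646L, nTotal)

  forgetOrdinal <- integer(nTotal)
  isForget <- conditions == "forget"
  forgetOrdinal[isForget] <- seq_len(sum(isForget)) - 1L

  rateMax <- p$baselineRateHz + p$visualAmpHz + p$memoryAmpHz +
    p$eyePositionModulationHz
  spikes <- vector("list", nTotal)
  for (i in seq_len(nTotal)) {
    set.seed(trialSeeds[i])
    f <- .trialRateFun(p, conditions[i], sacc[[conditions[i]]],
                       forgetOrdinal[i])
    spikes[[i]] <- .thinPoisson(f, rateMax, p$fixationOnMs, p$trialEndMs)
  }

  events <- data.frame(
    trialIndex = seq_len(nTotal) - 1L,
    blockId = unname(layout[conditions]),
    condition = conditions,
    saccadeId = unname(vapply(conditions, function(cc) sacc[[cc]],
                              character(1))),
    fixationOnMs = p$fixationOnMs,
    probeOnMs = ifelse(conditions %in% .PROBE_CONDITIONS, p$probeOnMs,
                       NA_real_),
    trialEndMs = p$trialEndMs)
  CellRecording(cellId = cellId, monkeyId = monkeyId, task = p$task,
                events = events, spikes = spikes)
}

#' Generate a synthetic population with ground truth
#'
#' Draws \code{nCells} units of which a fraction \code{memoryFraction}
#' carry a memory response; the rest have \code{memoryAmpHz = 0}. Each
#' cell gets its own seed derived from the master seed. A ground-truth
#' table records the generating parameters for recovery scoring.
#'
#' @param nCells number of units (may be 0).
#' @param memoryFraction fraction of units with a true memory response.
#' @param seed master seed.
#' @param paramSampler optional \code{function(i, isMemory, seed)}
#'   returning a [syntheticCellParams()] list; the default uses the
#'   standard parameters with \code{memoryAmpHz} zeroed for non-memory
#'   cells.
#' @param baseParams template parameters for the default sampler.
#' @param monkeyId identifier stamped on every cell.
#' @return list with \code{cells} (list of \linkS4class{CellRecording})
#'   and \code{truth} (data.frame: \code{cell_id}, \code{is_memory_true},
#'   \code{memory_amp_hz}, \code{memory_latency_ms},
#'   \code{decay_k_per_trial}).
#' @export
generatePopulation <- function(nCells, memoryFraction = 0.45, seed = 1L,
                               paramSampler = NULL,
                               baseParams = syntheticCellParams(),
                               monkeyId = "simA") {
  stopifnot(memoryFraction >= 0, memoryFraction <= 1, nCells >= 0)
  if (nCells == 0L)
    return(list(cells = list(),
                truth = data.frame(cell_id = character(0),
                                   is_memory_true = logical(0),
                                   memory_amp_hz = numeric(0),
                                   memory_latency_ms = numeric(0),
                                   decay_k_per_trial = numeric(0))))
  set.seed(seed %% 2147483646L + 1L)
  nMem <- round(nCells * memoryFraction)
  isMem <- sample(rep(c(TRUE, FALSE), c(nMem, nCells - nMem)))
  cellSeeds <- sample.int(2147483646L, nCells)
  if (is.null(paramSampler))
    paramSampler <- function(i, isMemory, seed) {
      p <- baseParams
      p$seed <- seed
      if (!isMemory) p$memoryAmpHz <- 0
      p
    }
  ids <- sprintf("cell%03d", seq_len(nCells))
  cells <- vector("list", nCells)
  truth <- vector("list", nCells)
  for (i in seq_len(nCells)) {
    p <- paramSampler(i, isMem[i], cellSeeds[i])
    cells[[i]] <- generateCell(p, cellId = ids[i], monkeyId = monkeyId)
    truth[[i]] <- data.frame(cell_id = ids[i], is_memory_true = isMem[i],
                             memory_amp_hz = p$memoryAmpHz,
                             memory_latency_ms = p$memoryLatencyMs,
                             decay_k_per_trial = p$decayKPerTrial)
  }
  list(cells = cells, truth = do.call(rbind, truth))
}
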