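#' Read recordings from the two-table CSV layout
#'
#' The on-disk format is two RFC-4180 CSV files in one directory:
#' \code{events.csv} with one row per trial (columns \code{cell_id},
#' \code{monkey_id}, \code{task}, \code{trial_index}, \code{block_id},
#' \code{condition}, \code{saccade_id}, \code{fixation_on_ms},
#' \code{probe_on_ms} — empty when no probe was shown — and
#' \code{trial_end_ms}) and \code{spikes.csv} with one row per spike
#' (\code{cell_id}, \code{trial_index}, \code{spike_time_ms}). Because every
#' trial owns an events row, trials with zero spikes survive the round trip.
#'
#' @param path directory containing \code{events.csv} and \code{spikes.csv}.
#' @return list of validated \linkS4class{CellRecording} objects, one per
#'   \code{cell_id}, trials ordered by \code{trial_index}.
#' @seealso [writeCells()]
#' @export
readCells <- function(path) {
  evFile <- file.path(path, "events.csv")
  spFile <- file.path(path, "spikes.csv")
  if (!file.exists(evFile) || !file.exists(spFile))
    stop("expected events.csv and spikes.csv under ", path)
  ev <- utils::read.csv(evFile, stringsAsFactors = FALSE)
  sp <- utils::read.csv(spFile, stringsAsFactors = FALSE)
  evNeeded <- c("cell_id", "monkey_id", "task", "trial_index", "block_id",
                "condition", "saccade_id", "fixation_on_ms", "probe_on_ms",
                "trial_end_ms")
  if (!all(evNeeded %in% names(ev)))
    stop("events.csv: missing column(s) ",
         paste(setdiff(evNeeded, names(ev)), collapse = ", "))
  spNeeded <- c("cell_id", "trial_index", "spike_time_ms")
  if (!all(spNeeded %in% names(sp)))
    stop("spikes.csv: missing column(s) ",
         paste(setdiff(spNeeded, names(sp)), collapse = ", "))
  badRow <- which(!is.finite(ev$trial_index) | !is.finite(ev$fixation_on_ms))
  if (length(badRow))
    stop("events.csv: malformed row at line ", badRow[1] + 1L)
  badSpike <- which(!is.finite(sp$spike_time_ms))
  if (length(badSpike))
    stop("spikes.csv: malformed row at line ", badSpike[1] + 1L)

  cells <- lapply(split(ev, ev$cell_id), function(evc) {
    evc <- evc[order(evc$trial_index), , drop = FALSE]
    spc <- sp[sp$cell_id == evc$cell_id[1], , drop = FALSE]
    unknown <- setdiff(spc$trial_index, evc$trial_index)
    if (length(unknown))
      stop(sprintf("spikes.csv: cell %s has spikes for unknown trial %s",
                   evc$cell_id[1], unknown[1]))
    spl <- split(spc$spike_time_ms, factor(spc$trial_index,
                                           levels = evc$trial_index))
    spikes <- unname(lapply(spl, function(v) sort(as.numeric(v))))
    CellRecording(
      cellId = evc$cell_id[1], monkeyId = evc$monkey_id[1],
      task = evc$task[1],
      events = data.frame(
        trialIndex = evc$trial_index, blockId = evc$block_id,
        condition = evc$condition, saccadeId = evc$saccade_id,
        fixationOnMs = evc$fixation_on_ms, probeOnMs = evc$probe_on_ms,
        trialEndMs = evc$trial_end_ms),
      spikes = spikes)
  })
  unname(cells[order(names(cells))])
}

#' Write recordings to the two-table CSV layout
#'
#' Inverse of [readCells()]: the written directory reads back to objects
#' equal to the input (lossless round trip, zero-spike trials included).
#'
#' @param cells list of \linkS4class{CellRecording} objects (may be empty,
#'   producing header-only files).
#' @param path output directory, created if needed.
#' @return \code{path}, invisibly.
#' @export
writeCells <- function(cells, path) {
  stopifnot(is.list(cells))
  for (x in cells) stopifnot(is(x, "CellRecording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  evRows <- lapply(cells, function(x) {
    ev <- x@events
    data.frame(cell_id = x@cellId, monkey_id = x@monkeyId, task = x@task,
               trial_index = ev$trialIndex, block_id = ev$blockId,
               condition = ev$condition, saccade_id = ev$saccadeId,
               fixation_on_ms = ev$fixationOnMs, probe_on_ms = ev$probeOnMs,
               trial_end_ms = ev$trialEndMs)
  })
  ev <- if (length(evRows)) do.call(rbind, evRows) else
    data.frame(cell_id = character(0), monkey_id = character(0),
               task = character(0), trial_index = integer(0),
               block_id = integer(0), condition = character(0),
               saccade_id = character(0), fixation_on_ms = numeric(0),
               probe_on_ms = numeric(0), trial_end_ms = numeric(0))
  spRows <- lapply(cells, function(x) {
    n <- lengths(x@spikes)
    data.frame(cell_id = rep(x@cellId, sum(n)),
               trial_index = rep(x@events$trialIndex, n),
               spike_time_ms = unlist(x@spikes, use.names = FALSE))
  })
  sp <- if (length(spRows)) do.call(rbind, spRows) else
    data.frame(cell_id = character(0), trial_index = integer(0),
               spike_time_ms = numeric(0))
  utils::write.csv(ev, file.path(path, "events.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE,
                   na = "")
  invisible(path)
}
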