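#' @include accessors.R
NULL

#' Label each press as success or failure
#'
#' A press is a success iff its duration strictly exceeds the session
#' criterion ("exceeded" is strict, so a press exactly at criterion is a
#' failure). When reward times are present the labels are cross-checked:
#' every rewarded press must be a success and vice versa. Idempotent.
#'
#' @param x a [BehavioralSession-class] or [HoldDataset-class] (labels every
#'   session).
#' @return The object with `pressOutcomes` populated.
#' @examples
#' s <- BehavioralSession("s1", "m1", "air", 1600,
#'                        pressOnsets = c(0, 3000),
#'                        pressOffsets = c(1700, 4600),
#'                        rewardTimes = 1700, sessionEndMs = 5000)
#' pressOutcomes(labelPressOutcomes(s))  # success (1700 > 1600), failure (1600)
#' @export
setMethod("labelPressOutcomes", "BehavioralSession", function(x) {
  dur <- pressDurations(x)
  out <- as.character(ifelse(dur > x@criterionMs, "success", "failure"))
  rewarded <- x@pressOffsets %in% x@rewardTimes
  if (any(rewarded & out != "success"))
    stopf("session %s: rewarded press labeled failure", x@sessionId)
  # note: unrewarded successes are legal only if the reward list is empty-by-
  # construction for that press; the class validity already forbids rewards on
  # sub-criterion presses, so only consistency of provided labels remains
  if (length(x@pressOutcomes) && !identical(x@pressOutcomes, unname(out)))
    stopf("session %s: existing pressOutcomes inconsistent with durations",
          x@sessionId)
  x@pressOutcomes <- unname(out)
  validObject(x)
  x
})

#' @rdname labelPressOutcomes
#' @export
setMethod("labelPressOutcomes", "HoldDataset", function(x) {
  x@sessions <- lapply(x@sessions, labelPressOutcomes)
  x
})

#' Drop units with too few spikes
#'
#' Mirrors the recording-quality inclusion rule: units with fewer than
#' `minSpikes` spikes in the whole session (default 1000) are removed.
#' Sessions are untouched; retained units keep their spike lists unchanged.
#'
#' @param dataset a [HoldDataset-class].
#' @param minSpikes minimum spike count for retention (`>=` keeps).
#' @return The filtered [HoldDataset-class].
#' @export
filterUnits <- function(dataset, minSpikes = 1000) {
  stopifnot(minSpikes >= 0)
  keep <- vapply(units(dataset), function(u) nSpikes(u) >= minSpikes,
                 logical(1))
  dataset@units <- dataset@units[keep]
  dataset
}

#' Keep each mouse's last sessions at a given criterion
#'
#' Selects, per mouse, the last `nLast` sessions run at `criterionMs`
#' (session order is the lexical order of session ids within mouse, which
#' the synthetic generator and the I/O layer both emit chronologically). A
#' mouse with fewer matching sessions contributes all of them, so every
#' mouse with any matching session keeps at least one; mice with none are
#' dropped with a warning. Units attached to dropped sessions are dropped.
#'
#' @param dataset a [HoldDataset-class].
#' @param criterionMs criterion to match (e.g. 1600).
#' @param nLast number of trailing sessions to keep per mouse (default 2).
#' @return The reduced [HoldDataset-class].
#' @export
selectAnalysisSessions <- function(dataset, criterionMs = 1600, nLast = 2) {
  ses <- sessions(dataset)
  if (!length(ses)) return(dataset)
  mice <- vapply(ses, mouseId, character(1))
  keepIds <- character(0)
  for (m in unique(mice)) {
    ids <- names(ses)[mice == m &
      vapply(ses, function(s) s@criterionMs == criterionMs, logical(1))]
    if (!length(ids)) {
      warnf("mouse %s has no sessions at criterion %g ms; dropped", m,
            criterionMs)
      next
    }
    ids <- sort(ids)
    keepIds <- c(keepIds, tail(ids, nLast))
  }
  dataset@sessions <- dataset@sessions[names(ses) %in% keepIds]
  keepUnit <- vapply(units(dataset),
                     function(u) u@sessionId %in% keepIds, logical(1))
  dataset@units <- dataset@units[keepUnit]
  dataset
}
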