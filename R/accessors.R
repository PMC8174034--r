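#' @include AllGenerics.R
NULL

#' Construct a BehavioralSession
#'
#' @param sessionId,mouseId identifiers.
#' @param group `"air"` or `"CIE"`.
#' @param criterionMs hold-duration criterion (ms).
#' @param pressOnsets,pressOffsets press interval endpoints (ms, 10-ms grid).
#' @param rewardTimes reward delivery times (ms).
#' @param sessionEndMs session end (ms); defaults to the last event.
#' @param pressOutcomes optional per-press `"success"`/`"failure"` labels.
#' @param maxRewards,maxSessionMs termination-rule bounds used in validation.
#' @return A validated [BehavioralSession-class].
#' @examples
#' s <- BehavioralSession("s1", "m1", "air", 800,
#'                        pressOnsets = c(0, 2000),
#'                        pressOffsets = c(1000, 2500),
#'                        rewardTimes = 1000, sessionEndMs = 3000)
#' pressDurations(s)
#' @export
BehavioralSession <- function(sessionId, mouseId, group, criterionMs,
                              pressOnsets, pressOffsets,
                              rewardTimes = numeric(0), sessionEndMs = NULL,
                              pressOutcomes = character(0),
                              maxRewards = 60, maxSessionMs = 90 * 60 * 1000) {
  if (is.null(sessionEndMs))
    sessionEndMs <- max(c(pressOffsets, rewardTimes, 0))
  new("BehavioralSession", sessionId = as.character(sessionId),
      mouseId = as.character(mouseId), group = as.character(group),
      criterionMs = as.numeric(criterionMs),
      pressOnsets = as.numeric(pressOnsets),
      pressOffsets = as.numeric(pressOffsets),
      rewardTimes = as.numeric(rewardTimes),
      sessionEndMs = as.numeric(sessionEndMs),
      pressOutcomes = as.character(pressOutcomes),
      maxRewards = maxRewards, maxSessionMs = maxSessionMs)
}

#' Construct a UnitRecording
#'
#' @param unitId,sessionId identifiers.
#' @param spikeTimes nondecreasing spike times (ms).
#' @return A validated [UnitRecording-class].
#' @export
UnitRecording <- function(unitId, sessionId, spikeTimes) {
  new("UnitRecording", unitId = as.character(unitId),
      sessionId = as.character(sessionId),
      spikeTimes = as.numeric(spikeTimes))
}

#' Construct a HoldDataset
#'
#' @param sessions list of [BehavioralSession-class].
#' @param units list of [UnitRecording-class].
#' @param provenance free-text origin note.
#' @return A validated [HoldDataset-class].
#' @export
HoldDataset <- function(sessions, units, provenance = "unspecified") {
  names(sessions) <- vapply(sessions, sessionId, character(1))
  names(units) <- vapply(units, unitId, character(1))
  new("HoldDataset", sessions = sessions, units = units,
      provenance = provenance)
}

## --- BehavioralSession accessors -------------------------------------------

#' @rdname accessors
setMethod("sessionId", "BehavioralSession", function(x) x@sessionId)
#' @rdname accessors
setMethod("mouseId", "BehavioralSession", function(x) x@mouseId)
#' @rdname accessors
setMethod("groupLabel", "BehavioralSession", function(x) x@group)
#' @rdname accessors
setMethod("criterionMs", "BehavioralSession", function(x) x@criterionMs)
#' @rdname accessors
setMethod("pressOnsets", "BehavioralSession", function(x) x@pressOnsets)
#' @rdname accessors
setMethod("pressOffsets", "BehavioralSession", function(x) x@pressOffsets)
#' @rdname accessors
setMethod("pressDurations", "BehavioralSession",
          function(x) x@pressOffsets - x@pressOnsets)
#' @rdname accessors
setMethod("rewardTimes", "BehavioralSession", function(x) x@rewardTimes)
#' @rdname accessors
setMethod("sessionEnd", "BehavioralSession", function(x) x@sessionEndMs)
#' @rdname accessors
setMethod("pressOutcomes", "BehavioralSession", function(x) x@pressOutcomes)
#' @rdname accessors
setMethod("nPresses", "BehavioralSession",
          function(x) length(x@pressOnsets))

setMethod("show", "BehavioralSession", function(object) {
  cat(sprintf(
    "BehavioralSession %s (mouse %s, %s)\n  criterion %g ms | %d presses, %d rewarded | ends %.1f min\n",
    object@sessionId, object@mouseId, object@group, object@criterionMs,
    length(object@pressOnsets), length(object@rewardTimes),
    object@sessionEndMs / 60000))
})

## --- UnitRecording accessors ------------------------------------------------

#' @rdname accessors
setMethod("unitId", "UnitRecording", function(x) x@unitId)
#' @rdname accessors
setMethod("sessionId", "UnitRecording", function(x) x@sessionId)
#' @rdname accessors
setMethod("spikeTimes", "UnitRecording", function(x) x@spikeTimes)
#' @rdname accessors
setMethod("nSpikes", "UnitRecording", function(x) length(x@spikeTimes))

setMethod("show", "UnitRecording", function(object) {
  cat(sprintf("UnitRecording %s (session %s): %d spikes\n",
              object@unitId, object@sessionId, length(object@spikeTimes)))
})

## --- HoldDataset accessors ---------------------------------------------------

#' @rdname accessors
setMethod("sessions", "HoldDataset", function(x) x@sessions)
#' @rdname accessors
setMethod("units", "HoldDataset", function(x) x@units)

setMethod("show", "HoldDataset", function(object) {
  grp <- table(vapply(object@sessions, groupLabel, character(1)))
  cat(sprintf("HoldDataset: %d sessions (%s), %d units\n  provenance: %s\n",
              length(object@sessions),
              paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
              length(object@units), object@provenance))
})

#' Look up the session a unit was recorded in
#'
#' @param dataset a [HoldDataset-class].
#' @param unit a [UnitRecording-class] or unit id.
#' @return The matching [BehavioralSession-class].
#' @export
sessionOf <- function(dataset, unit) {
  sid <- if (is(unit, "UnitRecording")) unit@sessionId else
    dataset@units[[unit]]@sessionId
  dataset@sessions[[sid]]
}

## --- Peth / ZScoredPeth / ModulationResult ----------------------------------

#' @rdname accessors
setMethod("unitId", "Peth", function(x) x@unitId)
#' @rdname accessors
setMethod("eventType", "Peth", function(x) x@eventType)
#' @rdname accessors
setMethod("rates", "Peth", function(x) x@rate)
#' @rdname accessors
setMethod("nEvents", "Peth", function(x) x@nEvents)
#' @rdname accessors
setMethod("binLeftEdges", "Peth", function(x)
  seq(x@windowMs[1], x@windowMs[2] - x@binWidthMs, by = x@binWidthMs))
#' @rdname accessors
setMethod("binCenters", "Peth", function(x)
  binLeftEdges(x) + x@binWidthMs / 2)

setMethod("show", "Peth", function(object) {
  cat(sprintf(
    "Peth (%s) unit %s: [%g, %g] ms, %g-ms bins, %d events%s\n",
    object@eventType, object@unitId, object@windowMs[1], object@windowMs[2],
    object@binWidthMs, object@nEvents,
    if (object@smoothed) ", smoothed" else ""))
})

#' @rdname accessors
setMethod("zScores", "ZScoredPeth", function(x) x@z)
#' @rdname accessors
setMethod("unitId", "ZScoredPeth", function(x) x@unitId)
#' @rdname accessors
setMethod("eventType", "ZScoredPeth", function(x) x@eventType)
#' @rdname accessors
setMethod("binLeftEdges", "ZScoredPeth", function(x)
  seq(x@windowMs[1], x@windowMs[2] - x@binWidthMs, by = x@binWidthMs))
#' @rdname accessors
setMethod("binCenters", "ZScoredPeth", function(x)
  binLeftEdges(x) + x@binWidthMs / 2)

#' @rdname accessors
setMethod("unitId", "ModulationResult", function(x) x@unitId)
#' @rdname accessors
setMethod("eventType", "ModulationResult", function(x) x@eventType)
#' @rdname accessors
setMethod("direction", "ModulationResult", function(x) x@direction)
#' @rdname accessors
setMethod("onsetLatency", "ModulationResult", function(x) x@onsetLatencyMs)

setMethod("show", "ModulationResult", function(object) {
  cat(sprintf("ModulationResult unit %s @ %s: %s%s\n",
              object@unitId, object@eventType, object@direction,
              if (object@direction == "none") "" else
                sprintf(" (onset %+g ms)", object@onsetLatencyMs)))
})

## --- DecodingResult -----------------------------------------------------------

#' @rdname accessors
setMethod("accuracy", "DecodingResult", function(x) x@accuracy)
#' @rdname accessors
setMethod("timeCenters", "DecodingResult", function(x) x@timeCenters)

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf(
    "DecodingResult (%s): %d time points, %d runs, %s nulls; peak accuracy %.3f\n",
    object@alignment, length(object@timeCenters), nrow(object@runAccuracies),
    if (length(object@nullAccuracies)) dim(object@nullAccuracies)[1] else 0,
    max(object@accuracy)))
})
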