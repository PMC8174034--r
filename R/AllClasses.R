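#' @include utils.R
NULL

GROUPS <- c("air", "CIE")
EVENT_TYPES <- c("press_onset", "press_offset", "reward")

#' BehavioralSession: one self-paced hold-down session
#'
#' Timestamped lever presses and rewards for a single session, the behavioral
#' ground truth every neural analysis aligns to. All times are milliseconds
#' from session start; behavioral events sit on the 10-ms acquisition grid.
#' Reward is delivered at press offset only when the hold duration strictly
#' exceeds `criterionMs`.
#'
#' @slot sessionId,mouseId character identifiers.
#' @slot group treatment group, `"air"` or `"CIE"`.
#' @slot criterionMs hold-duration criterion (ms), typically 800 or 1600.
#' @slot pressOnsets,pressOffsets paired, strictly ordered press interval
#'   endpoints (ms). Presses are half-open `[onset, offset)`.
#' @slot rewardTimes reward delivery timestamps; each equals the offset of
#'   exactly one press whose duration exceeds the criterion.
#' @slot sessionEndMs session termination time (ms).
#' @slot pressOutcomes optional `"success"`/`"failure"` label per press
#'   (length zero until [labelPressOutcomes()] is applied).
#' @slot maxRewards,maxSessionMs session termination rule bounds used for
#'   validation (defaults 60 rewards, 90 min).
#' @export
setClass("BehavioralSession",
  representation(
    sessionId = "character", mouseId = "character", group = "character",
    criterionMs = "numeric", pressOnsets = "numeric",
    pressOffsets = "numeric", rewardTimes = "numeric",
    sessionEndMs = "numeric", pressOutcomes = "character",
    maxRewards = "numeric", maxSessionMs = "numeric"
  ),
  prototype(pressOutcomes = character(0), maxRewards = 60,
            maxSessionMs = 90 * 60 * 1000)
)

setValidity("BehavioralSession", function(object) {
  on <- object@pressOnsets; off <- object@pressOffsets
  rw <- object@rewardTimes
  msgs <- character(0)
  if (!(object@group %in% GROUPS))
    msgs <- c(msgs, sprintf("group must be one of %s",
                            paste(GROUPS, collapse = "/")))
  if (length(object@criterionMs) != 1 || object@criterionMs <= 0)
    msgs <- c(msgs, "criterionMs must be a single positive number")
  if (length(on) != length(off))
    msgs <- c(msgs, "pressOnsets and pressOffsets must have equal length")
  else {
    if (length(on) > 1 && any(diff(on) <= 0))
      msgs <- c(msgs, "pressOnsets must be strictly increasing")
    if (any(off <= on))
      msgs <- c(msgs, "offset precedes onset (pressOffsets[i] must exceed pressOnsets[i])")
    if (length(on) > 1 && any(on[-1] < off[-length(off)]))
      msgs <- c(msgs, "presses overlap (onset i+1 before offset i)")
    ts <- c(on, off, rw)
    if (any(ts < 0)) msgs <- c(msgs, "negative behavioral timestamp")
    if (any(ts %% 10 != 0))
      msgs <- c(msgs, "behavioral timestamps must be multiples of 10 ms")
    if (any(ts > object@sessionEndMs))
      msgs <- c(msgs, "behavioral timestamp beyond sessionEndMs")
    dur <- off - on
    eligible <- off[dur > object@criterionMs]
    if (anyDuplicated(rw)) msgs <- c(msgs, "duplicated reward time")
    if (!all(rw %in% eligible))
      msgs <- c(msgs, "orphan reward (reward time matches no super-criterion press offset)")
    if (length(rw) > object@maxRewards)
      msgs <- c(msgs, sprintf("more than %d rewards", object@maxRewards))
    if (object@sessionEndMs > object@maxSessionMs)
      msgs <- c(msgs, "sessionEndMs exceeds maxSessionMs")
    po <- object@pressOutcomes
    if (length(po) && length(po) != length(on))
      msgs <- c(msgs, "pressOutcomes length mismatch")
    if (length(po) && !all(po %in% c("success", "failure")))
      msgs <- c(msgs, "pressOutcomes values must be success/failure")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' UnitRecording: sorted spike times of one unit in one session
#'
#' @slot unitId,sessionId character identifiers; `sessionId` must resolve to
#'   a [BehavioralSession-class] in the enclosing dataset.
#' @slot spikeTimes nondecreasing spike timestamps in ms (fractional allowed).
#' @export
setClass("UnitRecording",
  representation(unitId = "character", sessionId = "character",
                 spikeTimes = "numeric"))

setValidity("UnitRecording", function(object) {
  st <- object@spikeTimes
  if (is.unsorted(st)) return("spikeTimes must be nondecreasing")
  if (length(st) && st[1] < 0) return("negative spike time")
  TRUE
})

#' HoldDataset: sessions plus unit recordings
#'
#' @slot sessions named list of [BehavioralSession-class] (names = session ids).
#' @slot units named list of [UnitRecording-class] (names = unit ids).
#' @slot provenance free-text origin note.
#' @export
setClass("HoldDataset",
  representation(sessions = "list", units = "list", provenance = "character"),
  prototype(provenance = "unspecified"))

setValidity("HoldDataset", function(object) {
  sids <- vapply(object@sessions, function(s) s@sessionId, character(1))
  if (anyDuplicated(sids)) return("duplicated session ids")
  for (u in object@units) {
    if (sum(sids == u@sessionId) != 1)
      return(sprintf("unit %s references unknown session %s",
                     u@unitId, u@sessionId))
    ses <- object@sessions[[match(u@sessionId, sids)]]
    if (length(u@spikeTimes) && max(u@spikeTimes) > ses@sessionEndMs)
      return(sprintf("unit %s has spikes beyond session end", u@unitId))
  }
  TRUE
})

#' Peth: trial-averaged peri-event time histogram
#'
#' Firing rate (Hz) in fixed-width bins aligned to a behavioral event and
#' averaged over events. Bins are half-open `[left, left + width)`; the
#' default geometry is 20-ms bins spanning -10,000 to +10,000 ms (1000 bins).
#'
#' @slot unitId unit identifier.
#' @slot eventType alignment event: press_onset, press_offset or reward.
#' @slot windowMs two-element window around the event (ms).
#' @slot binWidthMs bin width (ms).
#' @slot rate trial-averaged rate per bin (Hz).
#' @slot nEvents number of alignment events averaged.
#' @slot smoothed whether the Gaussian moving average has been applied.
#' @export
setClass("Peth",
  representation(unitId = "character", eventType = "character",
                 windowMs = "numeric", binWidthMs = "numeric",
                 rate = "numeric", nEvents = "integer", smoothed = "logical"),
  prototype(smoothed = FALSE))

setValidity("Peth", function(object) {
  nb <- diff(object@windowMs) / object@binWidthMs
  if (!isTRUE(all.equal(nb, round(nb))))
    return("bin width must divide the window length")
  if (length(object@rate) != round(nb))
    return("rate length does not match window/binWidth")
  if (any(object@rate < -1e-12)) return("negative rate")
  if (object@nEvents < 1L) return("nEvents must be >= 1")
  if (!(object@eventType %in% EVENT_TYPES)) return("unknown eventType")
  TRUE
})

#' BaselineStats: reference statistics from the pre-press baseline epoch
#'
#' Summaries of the smoothed press-onset PETH over the baseline window
#' (-10,000 to -2,000 ms before press onset): mean, sample SD, and a 95%
#' interval of the 400 baseline bin values (empirical percentiles by default,
#' mean +/- 1.96 SD behind the `"parametric"` switch).
#'
#' @slot windowMs baseline window (ms relative to press onset).
#' @slot meanHz,sdHz,lower95Hz,upper95Hz baseline summaries (Hz).
#' @slot method `"percentile"` or `"parametric"`.
#' @export
setClass("BaselineStats",
  representation(windowMs = "numeric", meanHz = "numeric", sdHz = "numeric",
                 lower95Hz = "numeric", upper95Hz = "numeric",
                 method = "character"))

setValidity("BaselineStats", function(object) {
  if (object@sdHz < 0) return("sdHz must be nonnegative")
  if (object@lower95Hz > object@meanHz + 1e-9 ||
      object@upper95Hz < object@meanHz - 1e-9)
    return("95% interval must bracket the mean")
  TRUE
})

#' ModulationResult: event-locked modulation call for one unit
#'
#' Direction of significant firing-rate modulation relative to the baseline
#' 95% interval: `"up"` when at least four consecutive 20-ms bins exceed the
#' upper bound within the analysis window, `"down"` when four consecutive
#' bins fall below the lower bound, `"none"` otherwise. Onset latency is the
#' left edge of the first bin of the first qualifying run.
#'
#' @slot unitId,eventType identifiers.
#' @slot direction `"up"`, `"down"` or `"none"`.
#' @slot onsetLatencyMs onset latency (ms, signed relative to the event);
#'   `NA` when direction is `"none"`.
#' @slot upOnsetMs,downOnsetMs onsets of the first qualifying run in each
#'   direction separately (`NA` when absent); kept so dual-direction units
#'   retain both calls.
#' @slot windowMs analysis window searched (default -2000 to +3000 ms).
#' @export
setClass("ModulationResult",
  representation(unitId = "character", eventType = "character",
                 direction = "character", onsetLatencyMs = "numeric",
                 upOnsetMs = "numeric", downOnsetMs = "numeric",
                 windowMs = "numeric"))

setValidity("ModulationResult", function(object) {
  if (!(object@direction %in% c("up", "down", "none")))
    return("direction must be up/down/none")
  if (object@direction == "none" && !is.na(object@onsetLatencyMs))
    return("onset latency must be NA when direction is none")
  if (object@direction != "none") {
    if (is.na(object@onsetLatencyMs))
      return("onset latency required when modulated")
    if (object@onsetLatencyMs < object@windowMs[1] ||
        object@onsetLatencyMs >= object@windowMs[2])
      return("onset latency outside analysis window")
  }
  TRUE
})

#' ZScoredPeth: PETH converted to baseline z-scores
#'
#' @slot z z-score per bin; `NA` where undefined (degenerate zero-SD
#'   baseline with off-mean rate).
#' @slot baseline the [BaselineStats-class] used.
#' @slot unitId,eventType,windowMs,binWidthMs,nEvents geometry, as in
#'   [Peth-class].
#' @slot degenerate `TRUE` when the baseline SD was zero and some bins could
#'   not be z-scored; such units are excluded from averaged traces.
#' @export
setClass("ZScoredPeth",
  representation(z = "numeric", baseline = "BaselineStats",
                 unitId = "character", eventType = "character",
                 windowMs = "numeric", binWidthMs = "numeric",
                 nEvents = "integer", degenerate = "logical"),
  prototype(degenerate = FALSE))

#' PseudoTrialSet: one resampled pseudo-population draw
#'
#' Spike counts at 1-ms resolution for every unit on every pseudo-trial, a
#' synthetic simultaneous trial formed by pairing independently drawn press
#' events across units. Classes are balanced: `nPerClass` successes then
#' `nPerClass` failures.
#'
#' @slot units unit ids contributing (every unit contributes to every trial).
#' @slot nPerClass events drawn per class per unit.
#' @slot labels factor of trial labels, `success`/`failure`.
#' @slot counts integer array `units x trials x bins` of 1-ms spike counts.
#' @slot windowMs peri-event window (default -2000 to +10,000 ms).
#' @slot alignment `"press_onset"` or `"press_offset"`.
#' @export
setClass("PseudoTrialSet",
  representation(units = "character", nPerClass = "integer",
                 labels = "factor", counts = "array",
                 windowMs = "numeric", alignment = "character"))

setValidity("PseudoTrialSet", function(object) {
  d <- dim(object@counts)
  if (length(d) != 3) return("counts must be a 3-d array")
  if (d[1] != length(object@units)) return("counts dim 1 != number of units")
  if (d[2] != 2L * object@nPerClass) return("counts dim 2 != 2 * nPerClass")
  if (d[3] != diff(object@windowMs)) return("counts dim 3 != window length in ms")
  tab <- table(object@labels)
  if (length(tab) != 2 || tab[1] != tab[2]) return("labels must be balanced")
  TRUE
})

#' DecodingResult: sliding-window decoding accuracy with nulls
#'
#' @slot timeCenters window centers (ms relative to the alignment event).
#' @slot accuracy mean cross-validated accuracy per time point over runs.
#' @slot runAccuracies runs x time matrix of per-run accuracies.
#' @slot nullAccuracies nulls x runs x time array from shuffled labels
#'   (zero-extent when nulls were not computed).
#' @slot pRaw,pBH empirical one-sided p and its Benjamini-Hochberg
#'   adjustment per time point (NA until [significanceMask()] is applied).
#' @slot significantRaw,significantBH logical masks at `alpha`.
#' @slot alpha significance level.
#' @slot alignment alignment event of the underlying pseudo-trials.
#' @export
setClass("DecodingResult",
  representation(timeCenters = "numeric", accuracy = "numeric",
                 runAccuracies = "matrix", nullAccuracies = "array",
                 pRaw = "numeric", pBH = "numeric",
                 significantRaw = "logical", significantBH = "logical",
                 alpha = "numeric", alignment = "character"),
  prototype(alpha = 0.05))

setValidity("DecodingResult", function(object) {
  nt <- length(object@timeCenters)
  if (length(object@accuracy) != nt) return("accuracy length mismatch")
  if (any(object@accuracy < 0 | object@accuracy > 1))
    return("accuracies must lie in [0, 1]")
  for (s in c("pRaw", "pBH", "significantRaw", "significantBH")) {
    v <- slot(object, s)
    if (length(v) && length(v) != nt)
      return(sprintf("%s length mismatch", s))
  }
  TRUE
})
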