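#' @include accessors.R
NULL

#' Assign presses to within-session duration quartiles
#'
#' Rank-based split: presses are sorted by duration (ties broken by press
#' order) and divided into four contiguous rank blocks as equal as possible,
#' any remainder going to the earliest quartiles. This guarantees quartile
#' counts balanced within one press and is unambiguous under ties.
#' Boundaries are reported as the maximum duration within Q1-Q3.
#'
#' @param session a [BehavioralSession-class] with at least 4 presses.
#' @return A list of class `QuartileAssignment`: `sessionId`, `quartile`
#'   (integer 1-4 per press, in press order), `boundariesMs` (3 cut points),
#'   `meanDurationMs` (per-quartile mean), `counts`.
#' @export
assignQuartiles <- function(session) {
  dur <- pressDurations(session)
  n <- length(dur)
  if (n < 4) stopf("insufficient presses (%d < 4) for quartile assignment", n)
  ord <- order(dur, seq_len(n))
  base <- n %/% 4; rem <- n %% 4
  sizes <- rep(base, 4) + (seq_len(4) <= rem)
  qByRank <- rep(1:4, times = sizes)
  quartile <- integer(n)
  quartile[ord] <- qByRank
  boundaries <- vapply(1:3, function(q) max(dur[quartile == q]), numeric(1))
  meanDur <- vapply(1:4, function(q) mean(dur[quartile == q]), numeric(1))
  structure(list(sessionId = sessionId(session), quartile = quartile,
                 boundariesMs = boundaries, meanDurationMs = meanDur,
                 counts = as.integer(sizes)),
            class = "QuartileAssignment")
}

#' Fraction of presses containing at least one spike
#'
#' Presses are half-open `[onset, offset)`: a spike exactly at the offset
#' belongs to the post-press epoch and does not count.
#'
#' @param unit a [UnitRecording-class].
#' @param session the unit's [BehavioralSession-class].
#' @return Fraction in `[0, 1]`.
#' @export
spikePresenceFraction <- function(unit, session) {
  on <- pressOnsets(session); off <- pressOffsets(session)
  if (!length(on)) stopf("session has no presses")
  st <- spikeTimes(unit)
  has <- vapply(seq_along(on),
                function(i) countInInterval(st, on[i], off[i]) > 0,
                logical(1))
  mean(has)
}

#' Per-press spike proportions across four duration segments
#'
#' Splits each press into four equal-length sub-intervals (0-25%, 25-50%,
#' 50-75%, 75-100% of the duration; all half-open, the last closing at the
#' offset exclusively) and computes the fraction of that press's in-press
#' spikes falling in each. Presses with zero in-press spikes are undefined
#' (NA rows) and excluded from the per-unit means.
#'
#' @param unit a [UnitRecording-class].
#' @param session the unit's [BehavioralSession-class].
#' @return List: `perPress` (n x 4 matrix of proportions, NA rows for
#'   zero-spike presses), `unitMean` (length-4 unweighted mean over included
#'   presses), `nIncluded`.
#' @export
segmentSpikeProportions <- function(unit, session) {
  on <- pressOnsets(session); off <- pressOffsets(session)
  st <- spikeTimes(unit)
  perPress <- matrix(NA_real_, length(on), 4,
                     dimnames = list(NULL, paste0("seg", 1:4)))
  for (i in seq_along(on)) {
    edges <- on[i] + (off[i] - on[i]) * (0:4) / 4
    cnt <- vapply(1:4, function(s)
      countInInterval(st, edges[s], edges[s + 1]), numeric(1))
    tot <- sum(cnt)
    if (tot > 0) perPress[i, ] <- cnt / tot
  }
  inc <- !is.na(perPress[, 1])
  list(perPress = perPress,
       unitMean = if (any(inc)) colMeans(perPress[inc, , drop = FALSE])
                  else rep(NA_real_, 4),
       nIncluded = sum(inc))
}

#' Duration-quartile segment z-profiles for one unit
#'
#' For each duration quartile: segment firing rates (spike count in each
#' duration quarter divided by the quarter length, Hz) are z-scored against
#' a baseline proportionate to that quartile's mean press duration — the
#' window `[-mean duration, 0)` before each press onset, binned at 20 ms and
#' pooled over the quartile's presses for the baseline mean and SD. The
#' profile is the mean z per segment over the quartile's presses.
#'
#' @param unit a [UnitRecording-class].
#' @param session the unit's [BehavioralSession-class].
#' @param qa a [assignQuartiles()] result for the session.
#' @return List of 4 `SegmentProfile` lists (`unitId`, `quartile`, `meanZ`
#'   length 4, `nPresses`, `valid`); `valid = FALSE` flags a zero-SD
#'   baseline (profile NA, excluded from group means).
#' @export
quartileSegmentProfiles <- function(unit, session, qa) {
  stopifnot(inherits(qa, "QuartileAssignment"))
  on <- pressOnsets(session); off <- pressOffsets(session)
  st <- spikeTimes(unit)
  lapply(1:4, function(q) {
    idx <- which(qa$quartile == q)
    dbar <- qa$meanDurationMs[q]
    nb <- max(1L, floor(dbar / 20))
    baseRates <- unlist(lapply(idx, function(i) {
      edges <- on[i] - 20 * (nb:0)
      counts <- vapply(seq_len(nb), function(b)
        countInInterval(st, edges[b], edges[b + 1]), numeric(1))
      counts / 0.020
    }))
    mu <- mean(baseRates); sdev <- sd(baseRates)
    if (is.na(sdev) || sdev == 0) {
      return(structure(list(unitId = unitId(unit), quartile = q,
                            meanZ = rep(NA_real_, 4),
                            nPresses = length(idx), valid = FALSE),
                       class = "SegmentProfile"))
    }
    segZ <- vapply(1:4, function(s) {
      zs <- vapply(idx, function(i) {
        edges <- on[i] + (off[i] - on[i]) * (0:4) / 4
        segLenS <- (off[i] - on[i]) / 4 / 1000
        rate <- countInInterval(st, edges[s], edges[s + 1]) / segLenS
        (rate - mu) / sdev
      }, numeric(1))
      mean(zs)
    }, numeric(1))
    structure(list(unitId = unitId(unit), quartile = q, meanZ = segZ,
                   nPresses = length(idx), valid = TRUE),
              class = "SegmentProfile")
  })
}
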