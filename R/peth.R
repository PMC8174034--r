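#' @include accessors.R
NULL

DEFAULT_WINDOW <- c(-10000, 10000)
BASELINE_WINDOW <- c(-10000, -2000)
DETECT_WINDOW <- c(-2000, 3000)

# Event times for an alignment, optionally restricted by outcome.
eventTimesFor <- function(session, eventType, outcome = NULL) {
  ev <- switch(eventType,
    press_onset = pressOnsets(session),
    press_offset = pressOffsets(session),
    reward = rewardTimes(session),
    stopf("unknown eventType '%s'", eventType))
  if (!is.null(outcome) && eventType != "reward") {
    out <- pressOutcomes(session)
    if (!length(out)) stopf("press outcomes not labeled")
    ev <- ev[out == outcome]
  }
  ev
}

#' Bin spikes around events into a trial-averaged PETH
#'
#' Counts spikes in half-open bins `[event + left, event + left + width)`
#' and averages over events, yielding Hz. Windows of nearby events may
#' overlap, in which case a spike contributes to several events (self-paced
#' task; no proximity exclusion).
#'
#' @param unit a [UnitRecording-class] or a sorted numeric vector of spike
#'   times (ms).
#' @param eventTimes event timestamps (ms).
#' @param windowMs two-element window around each event (default
#'   -10,000..+10,000 ms).
#' @param binWidthMs bin width (ms, default 20); must divide the window.
#' @param eventType label stored on the result.
#' @return An unsmoothed [Peth-class].
#' @examples
#' p <- binSpikes(c(5, 25), eventTimes = 0, windowMs = c(-40, 40))
#' rates(p)  # 0 0 50 50
#' @export
binSpikes <- function(unit, eventTimes, windowMs = DEFAULT_WINDOW,
                      binWidthMs = 20, eventType = "press_onset") {
  spikes <- if (is(unit, "UnitRecording")) spikeTimes(unit) else
    as.numeric(unit)
  uid <- if (is(unit, "UnitRecording")) unitId(unit) else "unit"
  if (!length(eventTimes)) stopf("no events")
  nb <- diff(windowMs) / binWidthMs
  if (!isTRUE(all.equal(nb, round(nb))))
    stopf("bin width must divide the window length")
  nb <- as.integer(round(nb))
  counts <- integer(nb)
  for (e in eventTimes) {
    idx <- whichInInterval(spikes, e + windowMs[1], e + windowMs[2])
    if (!length(idx)) next
    b <- floor((spikes[idx] - e - windowMs[1]) / binWidthMs) + 1
    counts <- counts + tabulate(b, nb)
  }
  new("Peth", unitId = uid, eventType = eventType, windowMs = windowMs,
      binWidthMs = binWidthMs,
      rate = counts / (length(eventTimes) * binWidthMs / 1000),
      nEvents = length(eventTimes), smoothed = FALSE)
}

#' Smooth a PETH with a 3-bin Gaussian-weighted moving average
#'
#' The kernel is a normalized 3-tap Gaussian with SD `sigmaBins` bins
#' (default 0.4): neighbor weights `exp(-1/(2 sigma^2))` around a central 1,
#' normalized to sum to one. At the edges the kernel is truncated and
#' renormalized, so a constant PETH is preserved exactly.
#'
#' @param peth an unsmoothed [Peth-class].
#' @param sigmaBins Gaussian SD in bins.
#' @return The smoothed [Peth-class].
#' @export
smoothPeth <- function(peth, sigmaBins = 0.4) {
  if (peth@smoothed) stopf("PETH is already smoothed")
  w1 <- exp(-1 / (2 * sigmaBins^2))
  x <- peth@rate; n <- length(x)
  if (n == 1) return(peth)
  left <- c(0, x[-n]); right <- c(x[-1], 0)
  wsum <- rep(1 + 2 * w1, n); wsum[c(1, n)] <- 1 + w1
  peth@rate <- (w1 * left + x + w1 * right) / wsum
  peth@smoothed <- TRUE
  peth
}

#' Baseline statistics from the pre-press epoch of a smoothed PETH
#'
#' Summarizes the smoothed press-onset PETH over the baseline window
#' (-10,000 to -2,000 ms before press onset, 400 bins at 20 ms): mean,
#' sample SD, and a 95% interval. The interval is the empirical 2.5th/97.5th
#' percentile of the baseline bin values by default; `method = "parametric"`
#' uses mean +/- 1.96 SD instead.
#'
#' @param peth a smoothed press-onset-aligned [Peth-class] whose window
#'   covers the baseline epoch.
#' @param windowMs baseline window (ms).
#' @param method `"percentile"` (default) or `"parametric"`.
#' @return A [BaselineStats-class].
#' @export
baselineStats <- function(peth, windowMs = BASELINE_WINDOW,
                          method = c("percentile", "parametric")) {
  method <- match.arg(method)
  le <- binLeftEdges(peth)
  sel <- le >= windowMs[1] & le < windowMs[2]
  if (!any(sel)) stopf("PETH window does not cover the baseline epoch")
  x <- peth@rate[sel]
  m <- mean(x); s <- sd(x)
  if (is.na(s)) s <- 0
  if (method == "percentile") {
    q <- unname(quantile(x, c(0.025, 0.975), type = 7))
  } else {
    q <- m + c(-1.96, 1.96) * s
  }
  new("BaselineStats", windowMs = windowMs, meanHz = m, sdHz = s,
      lower95Hz = q[1], upper95Hz = q[2], method = method)
}

# First run of >= k consecutive TRUEs; returns start index or NA.
firstRunStart <- function(flags, k) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= k)
  if (!length(hit)) return(NA_integer_)
  ends[hit[1]] - r$lengths[hit[1]] + 1L
}

#' Detect event-locked firing-rate modulation
#'
#' Classifies a smoothed PETH against the baseline 95% interval: `"up"` when
#' at least `minRun` consecutive bins exceed the upper bound within the
#' analysis window (default -2000 to +3000 ms), `"down"` when `minRun`
#' consecutive bins fall below the lower bound. When both patterns occur the
#' direction of the earlier qualifying run wins (tie goes to up) and both
#' run onsets are kept. Onset latency is the left edge of the first bin of
#' the first qualifying run.
#'
#' @param peth a smoothed [Peth-class].
#' @param baseline [BaselineStats-class] from the same unit's press-onset
#'   alignment.
#' @param windowMs analysis window searched (ms).
#' @param minRun run length required (default 4 bins = 80 ms).
#' @return A [ModulationResult-class].
#' @export
detectModulation <- function(peth, baseline, windowMs = DETECT_WINDOW,
                             minRun = 4) {
  le <- binLeftEdges(peth)
  sel <- le >= windowMs[1] & le < windowMs[2]
  if (!any(sel)) stopf("PETH window does not cover the analysis window")
  x <- peth@rate[sel]; lev <- le[sel]
  iUp <- firstRunStart(x > baseline@upper95Hz, minRun)
  iDown <- firstRunStart(x < baseline@lower95Hz, minRun)
  upOnset <- if (is.na(iUp)) NA_real_ else lev[iUp]
  downOnset <- if (is.na(iDown)) NA_real_ else lev[iDown]
  direction <- if (is.na(iUp) && is.na(iDown)) "none"
    else if (is.na(iDown) || (!is.na(iUp) && iUp <= iDown)) "up"
    else "down"
  onset <- switch(direction, none = NA_real_, up = upOnset,
                  down = downOnset)
  new("ModulationResult", unitId = peth@unitId, eventType = peth@eventType,
      direction = direction, onsetLatencyMs = onset, upOnsetMs = upOnset,
      downOnsetMs = downOnset, windowMs = windowMs)
}

#' Convert a PETH to baseline z-scores
#'
#' `z = (rate - baseline mean) / baseline SD` per bin. With a degenerate
#' zero-SD baseline, bins equal to the mean get z = 0 and all others are
#' undefined (`NA`); such units are flagged `degenerate` and excluded from
#' averaged traces with a warning.
#'
#' @param peth a smoothed [Peth-class].
#' @param baseline a [BaselineStats-class].
#' @return A [ZScoredPeth-class].
#' @export
zscorePeth <- function(peth, baseline) {
  if (baseline@sdHz > 0) {
    z <- (peth@rate - baseline@meanHz) / baseline@sdHz
    degen <- FALSE
  } else {
    z <- ifelse(peth@rate == baseline@meanHz, 0, NA_real_)
    degen <- anyNA(z)
    if (degen)
      warnf("unit %s: zero baseline SD with off-mean bins; z undefined",
            peth@unitId)
  }
  new("ZScoredPeth", z = z, baseline = baseline, unitId = peth@unitId,
      eventType = peth@eventType, windowMs = peth@windowMs,
      binWidthMs = peth@binWidthMs, nEvents = peth@nEvents,
      degenerate = degen)
}

#' Success/failure split PETHs for one unit
#'
#' Builds separate smoothed PETHs from successful and failed presses and
#' z-scores each against the unit's all-press press-onset baseline (one
#' baseline period per unit, shared across alignments and splits). A class
#' with zero events yields `NULL` for that side.
#'
#' @param unit a [UnitRecording-class].
#' @param session the unit's outcome-labeled [BehavioralSession-class].
#' @param eventType alignment event (`"press_onset"` or `"press_offset"`).
#' @param windowMs,binWidthMs PETH geometry.
#' @param baseline optionally a precomputed all-press [BaselineStats-class];
#'   computed from the unit when omitted.
#' @return `list(success = , failure = )` of [ZScoredPeth-class] (or `NULL`
#'   where a class has no events).
#' @export
splitByOutcome <- function(unit, session, eventType = "press_onset",
                           windowMs = DEFAULT_WINDOW, binWidthMs = 20,
                           baseline = NULL) {
  if (!length(pressOutcomes(session)))
    session <- labelPressOutcomes(session)
  if (is.null(baseline)) {
    all <- smoothPeth(binSpikes(unit, pressOnsets(session), windowMs,
                                binWidthMs, eventType = "press_onset"))
    baseline <- baselineStats(all)
  }
  one <- function(outcome) {
    ev <- eventTimesFor(session, eventType, outcome)
    if (!length(ev)) {
      message(sprintf("unit %s: no %s presses; %s PETH absent",
                      unitId(unit), outcome, outcome))
      return(NULL)
    }
    zscorePeth(smoothPeth(binSpikes(unit, ev, windowMs, binWidthMs,
                                    eventType = eventType)), baseline)
  }
  list(success = one("success"), failure = one("failure"))
}

#' Task-event membership category of a unit
#'
#' Collapses the three per-event modulation calls into a direction-agnostic
#' membership in the power set of \{press_onset, press_offset, reward\}.
#'
#' @param onset,offset,reward [ModulationResult-class] for the three
#'   alignments.
#' @return Character scalar, e.g. `"press_onset+reward"`; `"none"` for
#'   task-unmodulated units.
#' @export
classifyUnitEvents <- function(onset, offset, reward) {
  res <- list(press_onset = onset, press_offset = offset, reward = reward)
  member <- names(res)[vapply(res, function(r) direction(r) != "none",
                              logical(1))]
  if (!length(member)) "none" else paste(member, collapse = "+")
}

#' Mean z in four 250-ms epoch bins
#'
#' Averages a z-scored PETH over four consecutive 250-ms bins of a named
#' epoch: `pre_onset` (-1000..0 ms before press onset), `post_offset` or
#' `post_reward` (0..+1000 ms after the event). Each 20-ms bin belongs to
#' the 250-ms bin containing its left edge, so bins alternate 13/12
#' constituents (250/20 = 12.5).
#'
#' @param z a [ZScoredPeth-class].
#' @param epoch epoch name (must match the alignment of `z`).
#' @return Named numeric of length 4 (`bin1`..`bin4`).
#' @export
epochSummary <- function(z,
                         epoch = c("pre_onset", "post_offset", "post_reward")) {
  epoch <- match.arg(epoch)
  expected <- c(pre_onset = "press_onset", post_offset = "press_offset",
                post_reward = "reward")[[epoch]]
  if (z@eventType != expected)
    stopf("epoch %s requires a %s-aligned PETH, got %s", epoch, expected,
          z@eventType)
  bounds <- if (epoch == "pre_onset") c(-1000, 0) else c(0, 1000)
  le <- binLeftEdges(z)
  if (bounds[1] < z@windowMs[1] || bounds[2] > z@windowMs[2])
    stopf("epoch outside PETH window")
  sel <- which(le >= bounds[1] & le < bounds[2])
  grp <- floor((le[sel] - bounds[1]) / 250) + 1
  v <- vapply(1:4, function(g) mean(z@z[sel[grp == g]]), numeric(1))
  setNames(v, paste0("bin", 1:4))
}

#' Group-averaged z-score traces
#'
#' Unweighted per-bin mean and SEM across units within each treatment group.
#' Degenerate (zero-SD baseline) units are excluded with a warning.
#'
#' @param zs list of [ZScoredPeth-class] with identical geometry.
#' @param groups character vector of group labels, one per element of `zs`.
#' @return A data frame `(group, time_ms, mean_z, sem_z, n_units)` with
#'   `time_ms` at bin centers.
#' @export
groupAverage <- function(zs, groups) {
  stopifnot(length(zs) == length(groups))
  degen <- vapply(zs, function(z) z@degenerate, logical(1))
  if (any(degen)) {
    warnf("excluding %d degenerate unit(s) from group average", sum(degen))
    zs <- zs[!degen]; groups <- groups[!degen]
  }
  if (!length(zs)) stopf("empty group")
  centers <- binCenters(zs[[1]])
  out <- lapply(unique(groups), function(g) {
    mat <- do.call(rbind, lapply(zs[groups == g], zScores))
    if (is.null(mat) || !nrow(mat)) stopf("empty group '%s'", g)
    data.frame(group = g, time_ms = centers, mean_z = colMeans(mat),
               sem_z = apply(mat, 2, sd) / sqrt(nrow(mat)),
               n_units = nrow(mat), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
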