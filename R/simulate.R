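#' @include params.R accessors.R
NULL

#' Simulate one self-paced hold-down session
#'
#' Generates alternating exponential inter-press gaps and log-normal hold
#' durations, both rounded to the 10-ms acquisition grid (minimum one tick),
#' rewards every press whose duration strictly exceeds the criterion, and
#' terminates the session at `maxRewards` rewards or `maxSessionMs`,
#' whichever comes first. Identical seeds produce identical sessions; the
#' caller's RNG state is untouched.
#'
#' @param params a [behaviorParams()] bundle.
#' @param seed integer seed.
#' @param sessionId,mouseId,group metadata for the emitted session.
#' @return A validated, outcome-labeled [BehavioralSession-class].
#' @export
simulateBehavior <- function(params, seed, sessionId = "sim_s1",
                             mouseId = "sim_m1", group = "air") {
  stopifnot(inherits(params, "BehaviorParams"))
  withSeed(seed, {
    onsets <- offsets <- numeric(0)
    t <- 0; nRew <- 0L
    sessionEnd <- params$maxSessionMs
    repeat {
      gap <- round(rexp(1, 1 / params$meanIpiMs) / 10) * 10
      dur <- snapToGrid(rlnorm(1, params$logDurationMu,
                               params$logDurationSigma))
      onset <- t + gap; offset <- onset + dur
      if (offset > params$maxSessionMs) break
      onsets <- c(onsets, onset); offsets <- c(offsets, offset)
      t <- offset
      if (dur > params$criterionMs) {
        nRew <- nRew + 1L
        if (nRew >= params$maxRewards) { sessionEnd <- offset; break }
      }
    }
    dur <- offsets - onsets
    labelPressOutcomes(BehavioralSession(
      sessionId = sessionId, mouseId = mouseId, group = group,
      criterionMs = params$criterionMs, pressOnsets = onsets,
      pressOffsets = offsets,
      rewardTimes = offsets[dur > params$criterionMs],
      sessionEndMs = sessionEnd, maxRewards = params$maxRewards,
      maxSessionMs = params$maxSessionMs))
  })
}

# Apply group-level multipliers to a unit's gains.
applyGroupEffect <- function(uparams, effect) {
  uparams$kernels <- lapply(uparams$kernels, function(k) {
    m <- if (k$anchor == "reward") effect$outcomeGainMultiplier
         else effect$pressGainMultiplier
    k$peakGain <- k$peakGain * m
    k
  })
  uparams$outcomeGainSuccess <-
    uparams$outcomeGainSuccess * effect$outcomeGainMultiplier
  uparams$outcomeGainFailure <-
    uparams$outcomeGainFailure * effect$outcomeGainMultiplier
  uparams
}

#' Instantaneous firing-rate profile of a simulated unit
#'
#' Evaluates the generative rate (Hz) at sorted times `t`: baseline rate
#' times the product of the active kernel gain envelopes, the hold
#' suppression profile inside presses (half-open `[onset, offset)`), and the
#' outcome gain over `(offset, offset + 1000]` ms. This is the exact rate
#' the thinning sampler in [simulateUnit()] draws from, so ground truth is
#' sufficient to recompute every rate profile.
#'
#' @param uparams a [unitParams()] bundle (after any group effect).
#' @param session an outcome-labeled [BehavioralSession-class].
#' @param t sorted evaluation times (ms).
#' @return Numeric rate (Hz) at each `t`.
#' @export
rateProfile <- function(uparams, session, t) {
  gain <- rep(1, length(t))
  eventsFor <- function(anchor) switch(anchor,
    press_onset = pressOnsets(session),
    press_offset = pressOffsets(session),
    reward = rewardTimes(session))
  for (k in uparams$kernels) {
    ev <- eventsFor(k$anchor)
    if (!length(ev)) next
    env <- rep(0, length(t))
    half <- 6 * k$widthMs
    for (e in ev) {
      c0 <- e + k$latencyMs
      idx <- whichInInterval(t, c0 - half, c0 + half)
      if (!length(idx)) next
      env[idx] <- pmax(env[idx],
                       exp(-(t[idx] - c0)^2 / (2 * k$widthMs^2)))
    }
    gain <- gain * (1 + (k$peakGain - 1) * env)
  }
  h <- uparams$hold
  on <- pressOnsets(session); off <- pressOffsets(session)
  out <- pressOutcomes(session)
  if (length(out) != length(on))
    stopf("rateProfile requires labeled press outcomes")
  for (i in seq_along(on)) {
    idx <- whichInInterval(t, on[i], off[i])
    if (length(idx)) {
      durS <- (off[i] - on[i]) / 1000
      depth <- h$depth * exp(-h$depthSlopePerS * durS)
      ramp <- rep(1, length(idx))
      if (h$rampFraction > 0 && h$prereleaseRampGain > 1) {
        rampStart <- off[i] - h$rampFraction * (off[i] - on[i])
        inRamp <- t[idx] >= rampStart
        frac <- (t[idx][inRamp] - rampStart) / (off[i] - rampStart)
        ramp[inRamp] <- 1 + (h$prereleaseRampGain - 1) * frac
      }
      gain[idx] <- gain[idx] * depth * ramp
    }
    oidx <- whichInInterval(t, off[i] + 1e-9, off[i] + 1000 + 1e-9)
    if (length(oidx)) {
      og <- if (out[i] == "success") uparams$outcomeGainSuccess
            else uparams$outcomeGainFailure
      gain[oidx] <- gain[oidx] * og
    }
  }
  uparams$baseRateHz * gain
}

# Upper bound on the achievable instantaneous rate: the profile maximum on a
# 5-ms grid inflated by 2%. All profile components (Gaussian envelopes with
# SD >= tens of ms, linear ramps, piecewise-constant gains) vary slowly
# relative to the grid, so the inflated grid maximum dominates the continuous
# maximum and thinning against it is exact.
maxRate <- function(uparams, session) {
  grid <- seq(0, sessionEnd(session), by = 5)
  1.02 * max(rateProfile(uparams, session, grid), uparams$baseRateHz)
}

#' Simulate one unit's spike train by Poisson thinning
#'
#' Draws an inhomogeneous Poisson spike train for the rate profile of
#' [rateProfile()]: a homogeneous process at the maximum achievable rate is
#' thinned by the ratio of the instantaneous to the maximum rate.
#' Deterministic under a fixed seed.
#'
#' @param uparams a [unitParams()] bundle.
#' @param session an outcome-labeled [BehavioralSession-class].
#' @param effect a [groupEffect()] applied to the gains (default: none).
#' @param seed integer seed.
#' @param unitId id for the emitted recording.
#' @param rateCeiling guard on the maximum achievable rate (Hz); parameter
#'   combinations exceeding it raise an error.
#' @return A [UnitRecording-class].
#' @export
simulateUnit <- function(uparams, session, effect = groupEffect(), seed,
                         unitId = "sim_u1", rateCeiling = 500) {
  stopifnot(inherits(uparams, "UnitParams"), inherits(effect, "GroupEffect"))
  up <- applyGroupEffect(uparams, effect)
  if (!length(pressOutcomes(session)))
    session <- labelPressOutcomes(session)
  rmax <- maxRate(up, session)
  if (rmax > rateCeiling)
    stopf("parameter error: maximum achievable rate %.1f Hz exceeds ceiling %g Hz",
          rmax, rateCeiling)
  Tms <- sessionEnd(session)
  withSeed(seed, {
    n <- rpois(1, rmax * Tms / 1000)
    cand <- sort(runif(n, 0, Tms))
    u <- runif(n)
    keep <- u <= rateProfile(up, session, cand) / rmax
    UnitRecording(unitId, sessionId(session), cand[keep])
  })
}

#' Simulate a two-group cohort with ground truth
#'
#' Simulates `nMicePerGroup` mice per treatment group, one session per
#' mouse, with `unitsPerMouse` units drawn from `prior` and group-level
#' multipliers from `effects`. Per-unit RNG substreams are derived from
#' `(seed, group, mouse, unit)`, so adding mice or units never alters
#' previously generated ones. Ground truth records every injected parameter.
#'
#' @param nMicePerGroup mice per group (default 9 per group, the cohort size
#'   the task was characterized with).
#' @param unitsPerMouse units recorded per mouse (default 8).
#' @param behavior a [behaviorParams()] bundle.
#' @param prior a [unitPrior()] distribution over unit parameters.
#' @param effects named list of [groupEffect()], one per group; the default
#'   encodes the dependence phenotype (CIE: press gains x1.5, outcome gains
#'   x0.5).
#' @param seed integer master seed.
#' @param rateCeiling guard passed to [simulateUnit()].
#' @return A list with elements `dataset` ([HoldDataset-class]) and
#'   `groundTruth` (class `SimulationGroundTruth`: `$kernels` data frame of
#'   injected kernel parameters, `$units` named list of effective
#'   [unitParams()], `$unitMeta` data frame, `$effects`, `$behavior`,
#'   `$prior`, `$seed`).
#' @export
simulateCohort <- function(nMicePerGroup = 9, unitsPerMouse = 8,
                           behavior = behaviorParams(), prior = unitPrior(),
                           effects = list(air = groupEffect(),
                                          CIE = groupEffect(1.5, 0.5)),
                           seed = 1, rateCeiling = 500) {
  stopifnot(nMicePerGroup >= 1, unitsPerMouse >= 1,
            all(names(effects) %in% GROUPS))
  sessionsL <- list(); unitsL <- list()
  kernelRows <- list(); unitParamsL <- list(); metaRows <- list()
  for (gi in seq_along(effects)) {
    g <- names(effects)[gi]
    for (mi in seq_len(nMicePerGroup)) {
      mID <- sprintf("%s_m%02d", g, mi)
      sID <- sprintf("%s_s1", mID)
      ses <- simulateBehavior(behavior, seed = mixSeed(seed, gi, mi),
                              sessionId = sID, mouseId = mID, group = g)
      sessionsL[[sID]] <- ses
      for (ui in seq_len(unitsPerMouse)) {
        uID <- sprintf("%s_u%02d", mID, ui)
        uSeed <- mixSeed(seed, gi, mi, ui)
        raw <- withSeed(uSeed, sampleUnitParams(prior))
        eff <- applyGroupEffect(raw, effects[[g]])
        rec <- simulateUnit(raw, ses, effect = effects[[g]],
                            seed = mixSeed(uSeed, 1), unitId = uID,
                            rateCeiling = rateCeiling)
        unitsL[[uID]] <- rec
        unitParamsL[[uID]] <- eff
        metaRows[[uID]] <- data.frame(
          unit_id = uID, session_id = sID, group = g,
          base_rate_hz = eff$baseRateHz, hold_depth = eff$hold$depth,
          hold_ramp_gain = eff$hold$prereleaseRampGain,
          hold_depth_slope = eff$hold$depthSlopePerS,
          outcome_gain_success = eff$outcomeGainSuccess,
          outcome_gain_failure = eff$outcomeGainFailure,
          stringsAsFactors = FALSE)
        kernelRows[[uID]] <- do.call(rbind, lapply(eff$kernels, function(k)
          data.frame(unit_id = uID, session_id = sID, group = g,
                     anchor = k$anchor,
                     true_direction = if (k$peakGain > 1) "up" else
                       if (k$peakGain < 1) "down" else "none",
                     peak_gain = k$peakGain, latency_ms = k$latencyMs,
                     width_ms = k$widthMs, stringsAsFactors = FALSE)))
      }
    }
  }
  dataset <- HoldDataset(unname(sessionsL), unname(unitsL),
                         provenance = sprintf("simulateCohort(seed = %d)", seed))
  gt <- structure(list(
    kernels = do.call(rbind, c(unname(kernelRows),
                               list(make.row.names = FALSE))),
    units = unitParamsL,
    unitMeta = do.call(rbind, c(unname(metaRows),
                                list(make.row.names = FALSE))),
    effects = effects, behavior = behavior, prior = prior, seed = seed),
    class = "SimulationGroundTruth")
  list(dataset = dataset, groundTruth = gt)
}
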