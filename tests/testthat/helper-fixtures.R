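# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# Minimal hand-built session; rewards derived from strict exceedance.
makeSession <- function(onsets, offsets, criterionMs = 800,
                        sessionId = "s1", mouseId = "m1", group = "air",
                        sessionEndMs = NULL, maxSessionMs = 90 * 60 * 1000,
                        maxRewards = 10000) {
  dur <- offsets - onsets
  labelPressOutcomes(
    BehavioralSession(sessionId, mouseId, group, criterionMs,
                      pressOnsets = onsets, pressOffsets = offsets,
                      rewardTimes = offsets[dur > criterionMs],
                      sessionEndMs = sessionEndMs,
                      maxSessionMs = maxSessionMs,
                      maxRewards = maxRewards))
}

# Session of n equal-duration presses spaced regularly, wide enough apart
# that +/-10 s PETH windows of adjacent presses do not overlap.
spacedSession <- function(nPresses = 100, durationMs = 500,
                          spacingMs = 20000, criterionMs = 1600,
                          group = "air", sessionId = "s1",
                          mouseId = "m1") {
  onsets <- 10000 + spacingMs * (seq_len(nPresses) - 1)
  offsets <- onsets + durationMs
  endMs <- max(offsets) + 11000
  makeSession(onsets, offsets, criterionMs, sessionId = sessionId,
              mouseId = mouseId, group = group, sessionEndMs = endMs,
              maxSessionMs = endMs)
}

# Homogeneous Poisson unit over a session (via the package generator with
# all gains at 1).
poissonUnit <- function(session, rateHz = 5, seed = 1, unitId = "u1") {
  simulateUnit(unitParams(baseRateHz = rateHz), session, seed = seed,
               unitId = unitId)
}

# Hand-built Peth from a rate vector (for detector/epoch unit tests).
ratePeth <- function(rate, windowMs = c(-10000, 10000), binWidthMs = 20,
                     unitId = "u1", eventType = "press_onset",
                     nEvents = 10L, smoothed = TRUE) {
  new("Peth", unitId = unitId, eventType = eventType, windowMs = windowMs,
      binWidthMs = binWidthMs, rate = rate, nEvents = nEvents,
      smoothed = smoothed)
}

# Hand-built BaselineStats.
makeBaseline <- function(meanHz, sdHz, lower, upper,
                         windowMs = c(-10000, -2000)) {
  new("BaselineStats", windowMs = windowMs, meanHz = meanHz, sdHz = sdHz,
      lower95Hz = lower, upper95Hz = upper, method = "percentile")
}

# A two-class decodable dataset: one session whose successful presses carry
# an outcome gain, units otherwise homogeneous.
outcomeGainDataset <- function(nUnits = 10, gainSuccess = 2,
                               gainFailure = 1, baseRateHz = 8,
                               seed = 1, behavior = behaviorParams()) {
  ses <- simulateBehavior(behavior, seed = seed)
  us <- lapply(seq_len(nUnits), function(i)
    simulateUnit(unitParams(baseRateHz = baseRateHz,
                            outcomeGainSuccess = gainSuccess,
                            outcomeGainFailure = gainFailure),
                 ses, seed = seed + 1000 + i,
                 unitId = sprintf("u%03d", i)))
  HoldDataset(list(ses), us)
}
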