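test_that("behavior simulation is seed-deterministic and valid", {
  bp <- behaviorParams()
  s1 <- simulateBehavior(bp, seed = 11)
  s2 <- simulateBehavior(bp, seed = 11)
  expect_identical(pressOnsets(s1), pressOnsets(s2))
  expect_identical(rewardTimes(s1), rewardTimes(s2))
  expect_true(validObject(s1))
  expect_s4_class(s1, "BehavioralSession")
  s3 <- simulateBehavior(bp, seed = 12)
  expect_false(identical(pressOnsets(s1), pressOnsets(s3)))
})

test_that("degenerate duration distributions hit the reward boundary cases", {
  # sigma -> 0 with median 2000 > criterion: every press rewarded, session
  # terminates at exactly maxRewards rewards
  bp <- behaviorParams(logDurationMu = log(2000), logDurationSigma = 0,
                       meanIpiMs = 2000)
  s <- simulateBehavior(bp, seed = 3)
  expect_identical(length(rewardTimes(s)), 60L)
  expect_identical(nPresses(s), 60L)
  expect_identical(sessionEnd(s), max(pressOffsets(s)))
  # median far below criterion in a short session: zero rewards
  bp0 <- behaviorParams(logDurationMu = log(100), logDurationSigma = 0.2,
                        meanIpiMs = 2000, maxSessionMs = 5 * 60 * 1000)
  s0 <- simulateBehavior(bp0, seed = 4)
  expect_length(rewardTimes(s0), 0)
  expect_gt(nPresses(s0), 10)
})

test_that("success fraction matches the log-normal tail probability", {
  bp <- behaviorParams()  # median 1200, sigma 0.6, criterion 1600
  s <- simulateBehavior(bp, seed = 2026)
  n <- nPresses(s)
  k <- sum(pressOutcomes(s) == "success")
  # success requires the 10-ms-rounded duration to exceed 1600, i.e. the
  # raw draw to be >= 1605; closed-form tail of the log-normal
  p <- 1 - plnorm(1605, bp$logDurationMu, bp$logDurationSigma)
  expect_gte(k, qbinom(0.025, n, p))
  expect_lte(k, qbinom(0.975, n, p))
})

test_that("all-gains-one units are homogeneous Poisson at the base rate", {
  ses <- spacedSession(nPresses = 20)
  u <- poissonUnit(ses, rateHz = 5, seed = 21)
  lambda <- 5 * sessionEnd(ses) / 1000
  expect_gte(nSpikes(u), qpois(0.005, lambda))
  expect_lte(nSpikes(u), qpois(0.995, lambda))
  # determinism
  expect_identical(spikeTimes(u), spikeTimes(poissonUnit(ses, 5, 21)))
})

test_that("hold suppression depth zero silences units inside every press", {
  ses <- spacedSession(nPresses = 30, durationMs = 2000)
  u <- simulateUnit(unitParams(baseRateHz = 20,
                               hold = holdSuppression(depth = 0)),
                    ses, seed = 5)
  st <- spikeTimes(u)
  for (i in seq_len(nPresses(ses))) {
    inside <- st >= pressOnsets(ses)[i] & st < pressOffsets(ses)[i]
    expect_identical(sum(inside), 0L)
  }
  expect_gt(nSpikes(u), 0)
})

test_that("an injected onset kernel reproduces its analytic PETH profile", {
  ses <- spacedSession(nPresses = 200, durationMs = 500)
  up <- unitParams(baseRateHz = 8,
                   kernels = list(gainKernel("press_onset", latencyMs = 0,
                                             widthMs = 100, peakGain = 3)))
  u <- simulateUnit(up, ses, seed = 31)
  p <- binSpikes(u, pressOnsets(ses))
  # analytic expectation at bin centers (events far apart; one press context)
  centers <- binCenters(p)
  expectHz <- rateProfile(up, ses, pressOnsets(ses)[1] + centers)
  peak <- which.max(expectHz)
  expect_gt(max(expectHz), 20)  # 3x base at the peak
  # averaged over 200 events, bin counts are Poisson(mean rate * 200 * 20 ms)
  sel <- which(abs(centers) < 400 | abs(centers + 5000) < 400)
  for (b in sel) {
    lam <- expectHz[b] * 200 * 0.020
    expect_gte(rates(p)[b] * 200 * 0.020, qpois(0.0005, lam))
    expect_lte(rates(p)[b] * 200 * 0.020, qpois(0.9995, lam))
  }
  # the empirical peak rate is close to 3x base
  expect_gt(max(rates(p)[abs(centers) < 300]), 0.8 * max(expectHz))
})

test_that("rate ceiling violations are rejected as parameter errors", {
  ses <- spacedSession(nPresses = 5)
  expect_error(
    simulateUnit(unitParams(baseRateHz = 400,
                            kernels = list(gainKernel("press_onset",
                                                      peakGain = 2))),
                 ses, seed = 1),
    "ceiling")
})

test_that("cohort simulation bookkeeping and substreams are stable", {
  bp <- behaviorParams(maxRewards = 10, maxSessionMs = 6 * 60 * 1000)
  res <- simulateCohort(nMicePerGroup = 1, unitsPerMouse = 1, behavior = bp,
                        seed = 9)
  expect_length(sessions(res$dataset), 2)
  expect_length(units(res$dataset), 2)
  expect_true(validObject(res$dataset))
  # determinism
  res2 <- simulateCohort(nMicePerGroup = 1, unitsPerMouse = 1, behavior = bp,
                         seed = 9)
  expect_identical(spikeTimes(units(res$dataset)[[1]]),
                   spikeTimes(units(res2$dataset)[[1]]))
  # adding units leaves earlier units untouched
  res3 <- simulateCohort(nMicePerGroup = 1, unitsPerMouse = 2, behavior = bp,
                         seed = 9)
  expect_identical(spikeTimes(units(res$dataset)[[1]]),
                   spikeTimes(units(res3$dataset)[[1]]))
  # injected group multipliers are recorded exactly: CIE/air press-kernel
  # gain ratio equals the configured 1.5 for matched unit substreams
  kt <- res$groundTruth$kernels
  expect_true(all(kt$peak_gain > 0))
  expect_setequal(unique(kt$anchor), EVENT_TYPES <- c("press_onset",
                                                      "press_offset",
                                                      "reward"))
  eff <- res$groundTruth$effects
  expect_identical(eff$CIE$pressGainMultiplier, 1.5)
  expect_identical(eff$CIE$outcomeGainMultiplier, 0.5)
})

test_that("ground truth suffices to recompute the exact rate profile", {
  bp <- behaviorParams(maxRewards = 5, maxSessionMs = 3 * 60 * 1000)
  res <- simulateCohort(nMicePerGroup = 1, unitsPerMouse = 1, behavior = bp,
                        seed = 77)
  uid <- names(units(res$dataset))[1]
  u <- units(res$dataset)[[uid]]
  ses <- sessionOf(res$dataset, u)
  up <- res$groundTruth$units[[uid]]
  r <- rateProfile(up, ses, seq(0, sessionEnd(ses), by = 50))
  expect_true(all(is.finite(r)) && all(r >= 0))
  expect_gt(max(r), up$baseRateHz)  # event-locked gains present
})
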