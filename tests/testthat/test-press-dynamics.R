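test_that("quartile assignment is a balanced rank split", {
  # 8 presses, durations 100..800: two per quartile
  ses <- makeSession(seq(0, 14000, by = 2000),
                     seq(0, 14000, by = 2000) + seq(100, 800, by = 100))
  qa <- assignQuartiles(ses)
  expect_equal(qa$counts, rep(2L, 4))
  expect_equal(qa$quartile, rep(1:4, each = 2))
  expect_equal(qa$boundariesMs, c(200, 400, 600))
  # 9 presses: remainder goes to the earliest quartile
  ses9 <- makeSession(seq(0, 16000, by = 2000),
                      seq(0, 16000, by = 2000) + seq(100, 900, by = 100))
  expect_equal(assignQuartiles(ses9)$counts, c(3L, 2L, 2L, 2L))
  # ties: all equal durations stay balanced, boundaries coincide
  sesT <- makeSession(seq(0, 14000, by = 2000),
                      seq(0, 14000, by = 2000) + 500)
  qaT <- assignQuartiles(sesT)
  expect_equal(qaT$counts, rep(2L, 4))
  expect_equal(qaT$boundariesMs, rep(500, 3))
  expect_error(assignQuartiles(makeSession(0, 100)), "insufficient")
})

test_that("quartile counts stay within one and partition the presses", {
  set.seed(3)
  for (n in c(4, 5, 7, 11, 40, 101)) {
    dur <- sample(seq(10, 3000, by = 10), n, replace = TRUE)
    on <- cumsum(c(0, head(dur, -1) + 500))
    ses <- makeSession(on, on + dur)
    qa <- assignQuartiles(ses)
    expect_equal(sum(qa$counts), n)
    expect_lte(diff(range(qa$counts)), 1)
    expect_setequal(unique(qa$quartile), 1:4)
  }
})

test_that("spike presence uses the half-open press interval", {
  ses <- makeSession(c(0, 200), c(100, 300))
  u <- UnitRecording("u1", "s1", 50)
  expect_equal(spikePresenceFraction(u, ses), 0.5)
  expect_equal(spikePresenceFraction(UnitRecording("u", "s1", numeric(0)),
                                     ses), 0)
  # spike exactly at an offset does not count for that press
  u2 <- UnitRecording("u2", "s1", 100)
  expect_equal(spikePresenceFraction(u2, ses), 0)
  expect_error(spikePresenceFraction(u, makeSession(numeric(0), numeric(0))),
               "no presses")
})

test_that("segment proportions normalize within press and exclude empty presses", {
  ses <- makeSession(0, 1000)
  u <- UnitRecording("u1", "s1", c(100, 600, 900))
  sp <- segmentSpikeProportions(u, ses)
  expect_equal(sp$perPress[1, ], c(seg1 = 1/3, seg2 = 0, seg3 = 1/3,
                                   seg4 = 1/3))
  # one spike in segment 2
  sp2 <- segmentSpikeProportions(UnitRecording("u", "s1", 300), ses)
  expect_equal(unname(sp2$perPress[1, ]), c(0, 1, 0, 0))
  # zero-spike presses are NA and excluded from unit means
  ses2 <- makeSession(c(0, 2000), c(1000, 3000))
  sp3 <- segmentSpikeProportions(UnitRecording("u", "s1", c(100, 600, 900)),
                                 ses2)
  expect_true(all(is.na(sp3$perPress[2, ])))
  expect_equal(sp3$nIncluded, 1)
  expect_equal(sum(sp3$unitMean), 1)
  # proportions of every included press sum to 1
  set.seed(5)
  on <- seq(0, 38000, by = 2000)
  ses3 <- makeSession(on, on + sample(seq(200, 1500, by = 10), 20))
  u3 <- UnitRecording("u", "s1", sort(runif(400, 0, 40000)))
  sp4 <- segmentSpikeProportions(u3, ses3)
  inc <- !is.na(sp4$perPress[, 1])
  expect_equal(unname(rowSums(sp4$perPress[inc, ])),
               rep(1, sum(inc)))
})

test_that("segment proportions are invariant to uniform time rescaling", {
  on <- c(0, 5000); dur <- c(1000, 2000)
  spikes <- c(100, 350, 900, 5200, 6900)
  ses <- makeSession(on, on + dur)
  u <- UnitRecording("u", "s1", spikes)
  sp <- segmentSpikeProportions(u, ses)
  sesS <- makeSession(on * 3, on * 3 + dur * 3)
  spS <- segmentSpikeProportions(UnitRecording("u", "s1", spikes * 3), sesS)
  expect_equal(sp$perPress, spS$perPress)
})

test_that("quartile segment z-profiles recover injected hold dynamics", {
  # varied durations so quartiles differ; spacing avoids window overlap
  set.seed(11)
  n <- 120
  on <- 10000 + 9000 * (seq_len(n) - 1)
  dur <- rep(c(400, 800, 1600, 3000), length.out = n)
  ses <- makeSession(on, on + dur, criterionMs = 1600,
                     sessionEndMs = max(on + dur) + 11000,
                     maxSessionMs = 90 * 60 * 1000 * 2)
  qa <- assignQuartiles(ses)

  # homogeneous unit: all segment z near 0 (baseline SD is the 20-ms-bin
  # Poisson SD, so z units are modest by construction)
  u0 <- poissonUnit(ses, rateHz = 50, seed = 31)
  pr0 <- quartileSegmentProfiles(u0, ses, qa)
  for (p in pr0) expect_lt(max(abs(p$meanZ)), 0.4)

  # flat suppression at depth 0.5: all four segments clearly negative
  # (expected z = (25 - 50) / sd ~ -0.5) and roughly equal
  uS <- simulateUnit(unitParams(baseRateHz = 50,
                                hold = holdSuppression(depth = 0.5)),
                     ses, seed = 32)
  prS <- quartileSegmentProfiles(uS, ses, qa)
  for (p in prS) {
    expect_true(all(p$meanZ < -0.25))
    expect_lt(diff(range(p$meanZ)), 0.5)
  }

  # pre-release ramp gain 2 over the final quarter: segment 4 above segment 3
  uR <- simulateUnit(unitParams(baseRateHz = 50,
                                hold = holdSuppression(depth = 0.5,
                                                       prereleaseRampGain = 2,
                                                       rampFraction = 0.25)),
                     ses, seed = 33)
  prR <- quartileSegmentProfiles(uR, ses, qa)
  for (p in prR) expect_gt(p$meanZ[4], p$meanZ[3])
})
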