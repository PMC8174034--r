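test_that("session inclusion requires ten successful presses", {
  mk <- function(nSucc, nFail) {
    n <- nSucc + nFail
    dur <- c(rep(2000, nSucc), rep(500, nFail))
    on <- cumsum(c(0, head(dur, -1) + 1000))
    makeSession(on, on + dur, criterionMs = 1600)
  }
  expect_false(sessionInclusion(mk(9, 5)))
  expect_true(sessionInclusion(mk(10, 5)))
  expect_false(sessionInclusion(makeSession(numeric(0), numeric(0),
                                            criterionMs = 1600)))
})

test_that("pseudo-populations have the documented shape and determinism", {
  ds <- outcomeGainDataset(nUnits = 2, seed = 5)
  pts <- buildPseudopopulation(ds, "press_offset", nPerClass = 3, seed = 1)
  expect_equal(dim(pts@counts), c(2, 6, 12000))
  expect_equal(as.character(pts@labels),
               rep(c("success", "failure"), each = 3))
  pts2 <- buildPseudopopulation(ds, "press_offset", nPerClass = 3, seed = 1)
  expect_identical(pts@counts, pts2@counts)
  pts3 <- buildPseudopopulation(ds, "press_offset", nPerClass = 3, seed = 2)
  expect_false(identical(pts@counts, pts3@counts))
  # a unit short of events in one class is dropped with a warning
  sesLow <- labelPressOutcomes(local({
    dur <- c(rep(2000, 12), rep(500, 2))
    on <- cumsum(c(0, head(dur, -1) + 1000))
    makeSession(on, on + dur, criterionMs = 1600)
  }))
  uLow <- poissonUnit(sesLow, 10, seed = 3, unitId = "low")
  sesLow@sessionId <- "slow"; uLow@sessionId <- "slow"
  ds2 <- HoldDataset(c(sessions(ds), list(sesLow)),
                     c(units(ds), list(uLow)))
  expect_warning(
    pts4 <- buildPseudopopulation(ds2, "press_offset", nPerClass = 3,
                                  seed = 1),
    "fewer than")
  expect_false("low" %in% pts4@units)
})

test_that("sliding features match brute-force window counts", {
  # uniform one spike per ms: every feature 1000 Hz
  counts <- array(1L, dim = c(2, 4, 1200))
  pts <- new("PseudoTrialSet", units = c("a", "b"), nPerClass = 2L,
             labels = factor(rep(c("success", "failure"), each = 2)),
             counts = counts, windowMs = c(-200, 1000),
             alignment = "press_offset")
  f <- slidingFeatures(pts)
  expect_true(all(f == 1000))
  expect_equal(attr(f, "centers"), seq(-100, 900, by = 100))
  # empty raster: all-zero features
  pts@counts <- array(0L, dim = c(2, 4, 1200))
  expect_true(all(slidingFeatures(pts) == 0))
  # brute-force oracle on random rasters
  set.seed(9)
  counts <- array(rpois(3 * 4 * 1200, 0.05), dim = c(3, 4, 1200))
  pts@counts <- counts; pts@units <- c("a", "b", "c"); pts@nPerClass <- 2L
  f <- slidingFeatures(pts, stepMs = 100, widthMs = 200)
  centers <- attr(f, "centers")
  for (ti in seq_along(centers)) {
    lo <- centers[ti] - 100; hi <- centers[ti] + 100
    bins <- which(seq(-200, 999) >= lo & seq(-200, 999) < hi)
    brute <- apply(counts[, , bins, drop = FALSE], c(1, 2), sum) * 5
    expect_equal(unname(f[, , ti]), unname(brute))
  }
})

test_that("disjoint constant-rate classes decode perfectly after the event", {
  # success presses carry a large outcome gain on an otherwise quiet unit
  ds <- outcomeGainDataset(nUnits = 6, gainSuccess = 40, gainFailure = 1,
                           baseRateHz = 1, seed = 8)
  res <- decodeTimecourse(ds, "press_offset", nPerClass = 20,
                          windowMs = c(-500, 1500), nRuns = 3, seed = 2)
  post <- res@timeCenters > 100 & res@timeCenters <= 900
  expect_true(all(res@accuracy[post] > 0.97))
  pre <- res@timeCenters < -100
  expect_true(all(abs(res@accuracy[pre] - 0.5) < 0.25))
  # determinism of the full decoding loop
  res2 <- decodeTimecourse(ds, "press_offset", nPerClass = 20,
                           windowMs = c(-500, 1500), nRuns = 3, seed = 2)
  expect_identical(res@runAccuracies, res2@runAccuracies)
})

test_that("label shuffling yields chance accuracy even on separable data", {
  ds <- outcomeGainDataset(nUnits = 6, gainSuccess = 40, gainFailure = 1,
                           baseRateHz = 1, seed = 8)
  nul <- nullDistributions(ds, "press_offset", nPerClass = 20,
                           windowMs = c(0, 1000), nNulls = 2, nRuns = 6,
                           seed = 4)
  expect_equal(dim(nul), c(2, 6, 9))
  m <- apply(nul, 3, mean)
  expect_true(all(abs(m - 0.5) < 0.15))
})

test_that("significance masks follow the pooled-null formula and BH ordering", {
  mkres <- function(obs, nulls) {
    new("DecodingResult", timeCenters = seq_along(obs) * 100,
        accuracy = obs,
        runAccuracies = matrix(obs, 1), nullAccuracies = nulls,
        pRaw = numeric(0), pBH = numeric(0), significantRaw = logical(0),
        significantBH = logical(0), alpha = 0.05,
        alignment = "press_offset")
  }
  set.seed(2)
  nulls <- array(runif(2 * 10 * 3, 0.4, 0.6), dim = c(2, 10, 3))
  # observed above every pooled null value: p = 1/(1 + 20)
  res <- significanceMask(mkres(c(0.99, 0.5, 0.99), nulls))
  expect_equal(res@pRaw[1], 1 / 21)
  expect_true(res@significantRaw[1])
  # observed at the null median: not significant
  expect_gt(res@pRaw[2], 0.3)
  expect_false(res@significantRaw[2])
  # BH mask is a subset of the raw mask
  set.seed(3)
  obs <- runif(12, 0.45, 0.7)
  nulls2 <- array(runif(5 * 20 * 12, 0.4, 0.6), dim = c(5, 20, 12))
  r2 <- significanceMask(mkres(obs, nulls2))
  expect_true(all(!r2@significantBH | r2@significantRaw))
  expect_error(significanceMask(mkres(obs,
                                      array(numeric(0), dim = c(0, 0, 12)))),
               "no null")
})
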