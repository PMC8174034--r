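test_that("binSpikes matches hand counts and averaging identities", {
  p <- binSpikes(c(5, 25), eventTimes = 0, windowMs = c(-40, 40))
  expect_equal(rates(p), c(0, 0, 50, 50))
  # duplicated events: averaging invariance
  p2 <- binSpikes(c(5, 25), eventTimes = c(0, 0), windowMs = c(-40, 40))
  expect_equal(rates(p2), rates(p))
  expect_error(binSpikes(c(5, 25), numeric(0)), "no events")
  expect_error(binSpikes(1:10, 0, windowMs = c(-30, 40), binWidthMs = 25),
               "divide")
})

test_that("binSpikes equals a brute-force per-event per-bin counting loop", {
  set.seed(42)
  for (rep in 1:20) {
    spikes <- sort(runif(500, 0, 50000))
    events <- sort(runif(8, 5000, 45000))
    w <- c(-500, 500); bw <- 20
    p <- binSpikes(spikes, events, windowMs = w, binWidthMs = bw)
    nb <- diff(w) / bw
    brute <- numeric(nb)
    for (e in events) for (b in seq_len(nb)) {
      lo <- e + w[1] + (b - 1) * bw; hi <- lo + bw
      brute[b] <- brute[b] + sum(spikes >= lo & spikes < hi)
    }
    expect_identical(rates(p), brute / (length(events) * bw / 1000))
  }
})

test_that("Gaussian 3-tap smoothing follows the kernel arithmetic", {
  # neighbor weight exp(-1/(2 * 0.4^2)); normalized taps
  w1 <- exp(-1 / (2 * 0.4^2))
  taps <- c(w1, 1, w1) / (1 + 2 * w1)
  x <- c(rep(0, 5), 1, rep(0, 5))
  sm <- smoothPeth(ratePeth(x, windowMs = c(0, 220), smoothed = FALSE))
  expect_equal(rates(sm)[5:7], c(taps[1], taps[2], taps[1]),
               tolerance = 1e-12)
  # impulse response mass preserved away from the edges
  expect_equal(sum(rates(sm)), 1, tolerance = 1e-12)
  # constant PETHs are invariant, including at the truncated edges
  smc <- smoothPeth(ratePeth(rep(7, 11), windowMs = c(0, 220),
                             smoothed = FALSE))
  expect_equal(rates(smc), rep(7, 11), tolerance = 1e-12)
  expect_error(smoothPeth(smc), "already smoothed")
})

test_that("baseline statistics summarize the 400 pre-press bins", {
  p <- ratePeth(rep(5, 1000))
  b <- baselineStats(p)
  expect_equal(c(b@meanHz, b@sdHz, b@lower95Hz, b@upper95Hz), c(5, 0, 5, 5))
  # alternating 4/6: mean 5, percentile interval [4, 6]
  p2 <- ratePeth(c(rep(c(4, 6), 200), rep(0, 600)))
  b2 <- baselineStats(p2)
  expect_equal(b2@meanHz, 5)
  expect_equal(c(b2@lower95Hz, b2@upper95Hz), c(4, 6))
  # parametric switch
  b3 <- baselineStats(p2, method = "parametric")
  expect_equal(b3@upper95Hz, 5 + 1.96 * b3@sdHz)
  # empirical interval covers ~95% of the baseline bins by construction
  set.seed(7)
  x <- rpois(400, 10) / 2
  p4 <- ratePeth(c(x, rep(0, 600)))
  b4 <- baselineStats(p4)
  cov <- mean(x >= b4@lower95Hz & x <= b4@upper95Hz)
  expect_gte(cov, 0.93); expect_lte(cov, 0.99)
})

test_that("modulation detection requires four consecutive out-of-bound bins", {
  bl <- makeBaseline(5, 1, 3, 7)
  base <- rep(5, 1000)
  mkRate <- function(at, len, value) {
    r <- base
    # detection window bins are indices 401..650 (left edges -2000..2980)
    idx <- 401 + (at + 2000) / 20 + seq_len(len) - 1
    r[idx] <- value
    r
  }
  # all bins at baseline mean: none
  expect_identical(direction(detectModulation(ratePeth(base), bl)), "none")
  # exactly 4 bins above upper95 starting at +100: up, onset +100
  m <- detectModulation(ratePeth(mkRate(100, 4, 10)), bl)
  expect_identical(direction(m), "up")
  expect_equal(onsetLatency(m), 100)
  # 3 bins only: none
  expect_identical(
    direction(detectModulation(ratePeth(mkRate(100, 3, 10)), bl)), "none")
  # 4 bins below lower95: down
  m2 <- detectModulation(ratePeth(mkRate(-400, 4, 1)), bl)
  expect_identical(direction(m2), "down")
  expect_equal(onsetLatency(m2), -400)
  # both directions: earlier run wins; both onsets retained
  r <- mkRate(-400, 4, 1)
  idx <- 401 + (500 + 2000) / 20 + 0:3
  r[idx] <- 10
  m3 <- detectModulation(ratePeth(r), bl)
  expect_identical(direction(m3), "down")
  expect_equal(m3@downOnsetMs, -400)
  expect_equal(m3@upOnsetMs, 500)
  # modulation outside the analysis window is ignored
  r2 <- base; r2[1:10] <- 50
  expect_identical(direction(detectModulation(ratePeth(r2), bl)), "none")
  # degenerate interval: any deviation counts against the percentile bounds
  bl0 <- makeBaseline(5, 0, 5, 5)
  m4 <- detectModulation(ratePeth(mkRate(0, 4, 5.1)), bl0)
  expect_identical(direction(m4), "up")
})

test_that("z-scoring uses the baseline mean and SD", {
  bl <- makeBaseline(5, 1, 3, 7)
  z <- zscorePeth(ratePeth(rep(7, 1000)), bl)
  expect_true(all(zScores(z) == 2))
  z0 <- zscorePeth(ratePeth(rep(5, 1000)), makeBaseline(5, 0, 5, 5))
  expect_true(all(zScores(z0) == 0))
  expect_false(z0@degenerate)
  expect_warning(
    zd <- zscorePeth(ratePeth(c(rep(5, 999), 6)), makeBaseline(5, 0, 5, 5)),
    "undefined")
  expect_true(zd@degenerate)
  # z of own baseline bins has sample mean 0 and SD 1 exactly
  set.seed(8)
  p <- smoothPeth(ratePeth(rpois(1000, 10) / 2, smoothed = FALSE))
  b <- baselineStats(p)
  z2 <- zscorePeth(p, b)
  le <- binLeftEdges(z2)
  zb <- zScores(z2)[le >= -10000 & le < -2000]
  expect_equal(mean(zb), 0, tolerance = 1e-10)
  expect_equal(sd(zb), 1, tolerance = 1e-10)
})

test_that("outcome splits preserve the event-weighted averaging identity", {
  ses <- labelPressOutcomes(spacedSession(nPresses = 30, durationMs = 2000,
                                          criterionMs = 1600))
  # alternate long/short by rebuilding: half successes
  on <- pressOnsets(ses)
  off <- on + rep(c(2000, 500), length.out = 30)
  ses <- labelPressOutcomes(makeSession(on, off, criterionMs = 1600,
                                        sessionEndMs = sessionEnd(ses),
                                        maxSessionMs = sessionEnd(ses)))
  u <- poissonUnit(ses, rateHz = 10, seed = 14)
  sp <- splitByOutcome(u, ses, eventType = "press_onset")
  expect_s4_class(sp$success, "ZScoredPeth")
  nS <- sp$success@nEvents; nF <- sp$failure@nEvents
  all <- zscorePeth(
    smoothPeth(binSpikes(u, pressOnsets(ses))),
    sp$success@baseline)
  expect_equal((zScores(sp$success) * nS + zScores(sp$failure) * nF) /
                 (nS + nF),
               zScores(all), tolerance = 1e-9)
  # a class with zero events is absent
  sesAll <- labelPressOutcomes(spacedSession(nPresses = 10,
                                             durationMs = 2000,
                                             criterionMs = 1600))
  expect_message(spA <- splitByOutcome(poissonUnit(sesAll, 5, 2), sesAll),
                 "failure")
  expect_null(spA$failure)
  expect_s4_class(spA$success, "ZScoredPeth")
})

test_that("unit event-membership categories cover the power set", {
  mk <- function(et, dir, onset = 0)
    new("ModulationResult", unitId = "u", eventType = et, direction = dir,
        onsetLatencyMs = if (dir == "none") NA_real_ else onset,
        upOnsetMs = NA_real_, downOnsetMs = NA_real_,
        windowMs = c(-2000, 3000))
  expect_identical(
    classifyUnitEvents(mk("press_onset", "up"), mk("press_offset", "none"),
                       mk("reward", "none")),
    "press_onset")
  expect_identical(
    classifyUnitEvents(mk("press_onset", "up"), mk("press_offset", "down"),
                       mk("reward", "up")),
    "press_onset+press_offset+reward")
  expect_identical(
    classifyUnitEvents(mk("press_onset", "none"), mk("press_offset", "none"),
                       mk("reward", "none")),
    "none")
})

test_that("epoch summaries average the constituent 20-ms bins on the 250-ms grid", {
  bl <- makeBaseline(0, 1, -2, 2)
  z2 <- zscorePeth(ratePeth(rep(2, 1000)), bl)
  expect_equal(unname(epochSummary(z2, "pre_onset")), rep(2, 4))
  # linear ramp: increasing bin means
  r <- seq(0, 1, length.out = 1000)
  zl <- zscorePeth(ratePeth(r), bl)
  expect_true(all(diff(epochSummary(zl, "pre_onset")) > 0))
  # brute-force oracle: mean over 20-ms bins grouped by the 250-ms bin
  # containing their left edge
  set.seed(10)
  zr <- zscorePeth(ratePeth(runif(1000, 0, 20)), bl)
  le <- binLeftEdges(zr)
  sel <- le >= -1000 & le < 0
  grp <- floor((le[sel] + 1000) / 250) + 1
  brute <- tapply(zScores(zr)[sel], grp, mean)
  expect_equal(unname(epochSummary(zr, "pre_onset")), as.numeric(brute))
  # 13/12 alternation of constituents
  expect_equal(as.vector(table(grp)), c(13L, 12L, 13L, 12L))
  # alignment mismatch is an error
  expect_error(epochSummary(zr, "post_offset"), "press_offset")
  # epoch outside the window is an error
  znarrow <- zscorePeth(ratePeth(rep(1, 10), windowMs = c(-100, 100)), bl)
  expect_error(epochSummary(znarrow, "pre_onset"), "window")
})

test_that("group averages are unweighted means with SEM across units", {
  bl <- makeBaseline(0, 1, -2, 2)
  mkz <- function(v) zscorePeth(ratePeth(rep(v, 4), windowMs = c(-40, 40)), bl)
  zz <- list(mkz(1), mkz(3), mkz(2))
  zz[[1]]@z <- c(1, 3, 1, 3); zz[[2]]@z <- c(3, 1, 3, 1)
  ga <- groupAverage(zz[1:2], c("air", "air"))
  expect_equal(ga$mean_z, rep(2, 4))
  # single unit: trace equals the unit's
  g1 <- groupAverage(zz[3], "CIE")
  expect_equal(g1$mean_z, zScores(zz[[3]]))
  # identical traces: SEM 0
  g2 <- groupAverage(list(mkz(2), mkz(2), mkz(2)), rep("air", 3))
  expect_equal(g2$sem_z, rep(0, 4))
  expect_error(groupAverage(list(), character(0)), "empty")
})
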