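#' @include accessors.R
NULL

DECODE_WINDOW <- c(-2000, 10000)

#' Decoding inclusion rule for a session
#'
#' A session enters the decoding analysis only if at least `minSuccesses`
#' presses exceeded the criterion (labels are computed on the fly when
#' absent).
#'
#' @param session a [BehavioralSession-class].
#' @param minSuccesses minimum successful press count (default 10).
#' @return Logical flag.
#' @export
sessionInclusion <- function(session, minSuccesses = 10) {
  if (!length(pressOutcomes(session)))
    session <- labelPressOutcomes(session)
  sum(pressOutcomes(session) == "success") >= minSuccesses
}

# Units eligible for decoding with their per-class event times.
decodingUnits <- function(dataset, alignment, minSuccesses) {
  dataset <- labelPressOutcomes(dataset)
  keep <- list()
  for (u in units(dataset)) {
    ses <- sessionOf(dataset, u)
    if (!sessionInclusion(ses, minSuccesses)) next
    keep[[unitId(u)]] <- list(
      unit = u,
      success = eventTimesFor(ses, alignment, "success"),
      failure = eventTimesFor(ses, alignment, "failure"))
  }
  keep
}

#' Build one pseudo-population resampling draw
#'
#' For each eligible unit independently draws `nPerClass` success and
#' `nPerClass` failure events without replacement; the k-th drawn event of
#' every unit is stacked into pseudo-trial k, yielding a synthetic
#' simultaneous trial set across units recorded in different sessions.
#' Counts are binned at 1 ms over `windowMs`. Units with fewer than
#' `nPerClass` events in either class are dropped with a warning.
#'
#' @param dataset a [HoldDataset-class].
#' @param alignment `"press_onset"` or `"press_offset"`.
#' @param nPerClass events per class per unit; default is the minimum
#'   per-class event count over eligible units.
#' @param windowMs peri-event window (default -2000..+10,000 ms).
#' @param seed integer seed (per-unit substreams derive from it).
#' @param minSuccesses session inclusion threshold (default 10).
#' @return A [PseudoTrialSet-class].
#' @export
buildPseudopopulation <- function(dataset, alignment = "press_offset",
                                  nPerClass = NULL,
                                  windowMs = DECODE_WINDOW, seed = 1,
                                  minSuccesses = 10) {
  stopifnot(alignment %in% c("press_onset", "press_offset"))
  cand <- decodingUnits(dataset, alignment, minSuccesses)
  if (!length(cand)) stopf("no units eligible for decoding")
  perClass <- vapply(cand, function(x)
    min(length(x$success), length(x$failure)), numeric(1))
  if (is.null(nPerClass)) nPerClass <- min(perClass)
  nPerClass <- as.integer(nPerClass)
  if (nPerClass < 1) stopf("nPerClass must be >= 1 (no events available)")
  low <- perClass < nPerClass
  if (any(low)) {
    warnf("dropping %d unit(s) with fewer than %d events in a class",
          sum(low), nPerClass)
    cand <- cand[!low]
  }
  if (!length(cand)) stopf("no units remain after the event-count filter")
  nb <- as.integer(diff(windowMs))
  nTr <- 2L * nPerClass
  counts <- array(0L, dim = c(length(cand), nTr, nb))
  for (ui in seq_along(cand)) {
    x <- cand[[ui]]
    ev <- withSeed(mixSeed(seed, ui), {
      c(sample(x$success, nPerClass), sample(x$failure, nPerClass))
    })
    st <- spikeTimes(x$unit)
    for (k in seq_len(nTr)) {
      idx <- whichInInterval(st, ev[k] + windowMs[1], ev[k] + windowMs[2])
      if (!length(idx)) next
      b <- floor(st[idx] - ev[k] - windowMs[1]) + 1
      counts[ui, k, ] <- counts[ui, k, ] + tabulate(b, nb)
    }
  }
  new("PseudoTrialSet", units = names(cand), nPerClass = nPerClass,
      labels = factor(rep(c("success", "failure"), each = nPerClass),
                      levels = c("success", "failure")),
      counts = counts, windowMs = windowMs, alignment = alignment)
}

#' Sliding-window rate features from a pseudo-trial set
#'
#' Feature at time center t = spike count in `[t - width/2, t + width/2)`
#' per unit per pseudo-trial, in Hz. Centers are every `stepMs` across the
#' window wherever the full width fits.
#'
#' @param pts a [PseudoTrialSet-class].
#' @param stepMs step between window centers (default 100 ms).
#' @param widthMs window width (default 200 ms).
#' @return Array `units x trials x timepoints` with attribute `centers`.
#' @export
slidingFeatures <- function(pts, stepMs = 100, widthMs = 200) {
  w <- pts@windowMs
  centers <- seq(w[1] + widthMs / 2, w[2] - widthMs / 2, by = stepMs)
  d <- dim(pts@counts)
  m <- matrix(pts@counts, d[1] * d[2], d[3])
  cs <- t(apply(m, 1, cumsum))
  lo <- round(centers - widthMs / 2 - w[1])       # bins strictly before start
  hi <- round(centers + widthMs / 2 - w[1])       # bins up to end
  feat <- (cs[, hi, drop = FALSE] -
           (if (all(lo > 0)) cs[, lo, drop = FALSE] else
             sapply(lo, function(j) if (j > 0) cs[, j] else rep(0, nrow(cs))))) *
          (1000 / widthMs)
  arr <- array(feat, dim = c(d[1], d[2], length(centers)))
  attr(arr, "centers") <- centers
  arr
}

# Core resampling loop shared by observed and null decoding.
decodeRuns <- function(dataset, alignment, nPerClass, windowMs, stepMs,
                       widthMs, nRuns, nSplits, cost, seed, minSuccesses,
                       shuffle = FALSE) {
  runAcc <- NULL; centers <- NULL
  for (r in seq_len(nRuns)) {
    pts <- buildPseudopopulation(dataset, alignment, nPerClass, windowMs,
                                 seed = mixSeed(seed, 101, r), minSuccesses)
    feats <- slidingFeatures(pts, stepMs, widthMs)
    if (is.null(centers)) {
      centers <- attr(feats, "centers")
      runAcc <- matrix(NA_real_, nRuns, length(centers))
    }
    labels <- pts@labels
    if (shuffle)
      labels <- withSeed(mixSeed(seed, 202, r), sample(labels))
    nTr <- length(labels)
    folds <- withSeed(mixSeed(seed, 303, r), {
      f <- integer(nTr)
      for (cl in levels(labels)) {
        i <- which(labels == cl)
        f[i] <- sample(rep_len(seq_len(nSplits), length(i)))
      }
      f
    })
    nU <- dim(feats)[1]
    for (ti in seq_along(centers)) {
      X <- t(matrix(feats[, , ti], nU, nTr))
      accs <- numeric(0)
      for (fd in seq_len(nSplits)) {
        tr <- folds != fd
        ytr <- labels[tr]
        if (length(unique(ytr)) < 2 || !any(!tr)) next
        mu <- colMeans(X[tr, , drop = FALSE])
        sdv <- apply(X[tr, , drop = FALSE], 2, sd)
        sdv[sdv == 0 | is.na(sdv)] <- 1
        Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
        fit <- e1071::svm(Xs[tr, , drop = FALSE], ytr, kernel = "linear",
                          cost = cost, scale = FALSE)
        pred <- predict(fit, Xs[!tr, , drop = FALSE])
        accs <- c(accs, mean(pred == labels[!tr]))
      }
      runAcc[r, ti] <- if (length(accs)) mean(accs) else NA_real_
    }
  }
  list(centers = centers, runAcc = runAcc)
}

#' Sliding-window decoding of press success
#'
#' Pseudo-population decoding of press outcome: per resampling run, events
#' are redrawn per unit ([buildPseudopopulation()]), features are sliding
#' 200-ms spike-count windows stepped every 100 ms, each unit's features are
#' z-scored by training-fold statistics, and a linear maximum-margin
#' classifier (SVM, fixed cost) is trained and tested over `nSplits`
#' stratified cross-validation folds. Reported accuracy is the mean over
#' folds and runs. Optionally computes `nNulls` shuffled-label null
#' distributions of the identical procedure.
#'
#' @param dataset a [HoldDataset-class].
#' @param alignment `"press_onset"` or `"press_offset"`.
#' @param nPerClass events per class per unit (default: minimum available).
#' @param windowMs peri-event window.
#' @param stepMs,widthMs sliding-window geometry (100/200 ms).
#' @param nRuns resampling runs (default 500).
#' @param nSplits cross-validation folds (default 10).
#' @param cost SVM regularization constant (default 1).
#' @param nNulls shuffled-label null distributions to compute (default 0).
#' @param nullRuns runs per null distribution (default `nRuns`).
#' @param seed integer seed; observed and null streams are derived from it.
#' @param minSuccesses session inclusion threshold.
#' @return A [DecodingResult-class] (significance slots empty until
#'   [significanceMask()] is applied).
#' @export
decodeTimecourse <- function(dataset, alignment = "press_offset",
                             nPerClass = NULL, windowMs = DECODE_WINDOW,
                             stepMs = 100, widthMs = 200, nRuns = 500,
                             nSplits = 10, cost = 1, nNulls = 0,
                             nullRuns = nRuns, seed = 1, minSuccesses = 10) {
  obs <- decodeRuns(dataset, alignment, nPerClass, windowMs, stepMs,
                    widthMs, nRuns, nSplits, cost, seed, minSuccesses,
                    shuffle = FALSE)
  nullArr <- array(numeric(0), dim = c(0, 0, length(obs$centers)))
  if (nNulls > 0) {
    nullArr <- array(NA_real_,
                     dim = c(nNulls, nullRuns, length(obs$centers)))
    for (j in seq_len(nNulls)) {
      nl <- decodeRuns(dataset, alignment, nPerClass, windowMs, stepMs,
                       widthMs, nullRuns, nSplits, cost,
                       seed = mixSeed(seed, 7000, j), minSuccesses,
                       shuffle = TRUE)
      nullArr[j, , ] <- nl$runAcc
    }
  }
  new("DecodingResult", timeCenters = obs$centers,
      accuracy = colMeans(obs$runAcc, na.rm = TRUE),
      runAccuracies = obs$runAcc, nullAccuracies = nullArr,
      pRaw = numeric(0), pBH = numeric(0),
      significantRaw = logical(0), significantBH = logical(0),
      alpha = 0.05, alignment = alignment)
}

#' Shuffled-label null accuracy distributions
#'
#' Runs the identical decoding procedure with class labels randomly
#' permuted once per resampling run, `nNulls` times.
#'
#' @inheritParams decodeTimecourse
#' @param nNulls number of null distributions (default 5).
#' @return Array `nNulls x nRuns x timepoints` with attribute `centers`.
#' @export
nullDistributions <- function(dataset, alignment = "press_offset",
                              nPerClass = NULL, windowMs = DECODE_WINDOW,
                              stepMs = 100, widthMs = 200, nNulls = 5,
                              nRuns = 500, nSplits = 10, cost = 1,
                              seed = 1, minSuccesses = 10) {
  out <- NULL; centers <- NULL
  for (j in seq_len(nNulls)) {
    nl <- decodeRuns(dataset, alignment, nPerClass, windowMs, stepMs,
                     widthMs, nRuns, nSplits, cost,
                     seed = mixSeed(seed, 7000, j), minSuccesses,
                     shuffle = TRUE)
    if (is.null(out)) {
      centers <- nl$centers
      out <- array(NA_real_, dim = c(nNulls, nRuns, length(centers)))
    }
    out[j, , ] <- nl$runAcc
  }
  attr(out, "centers") <- centers
  out
}

#' Significance masks against the pooled null
#'
#' Empirical one-sided p per time point with add-one correction,
#' `p = (1 + #\{null >= observed\}) / (1 + n_null)` over the pooled
#' null-distribution accuracies, plus a Benjamini-Hochberg adjustment
#' across time points. The BH mask is never more liberal than the raw mask.
#'
#' @param result a [DecodingResult-class] carrying null accuracies (use
#'   `nNulls > 0` in [decodeTimecourse()]).
#' @param alpha significance level (default 0.05).
#' @return The [DecodingResult-class] with `pRaw`, `pBH` and both masks
#'   filled.
#' @export
significanceMask <- function(result, alpha = 0.05) {
  if (!length(result@nullAccuracies))
    stopf("DecodingResult carries no null distributions")
  nt <- length(result@timeCenters)
  d <- dim(result@nullAccuracies)
  nNull <- d[1] * d[2]
  p <- vapply(seq_len(nt), function(ti) {
    nv <- result@nullAccuracies[, , ti]
    (1 + sum(nv >= result@accuracy[ti], na.rm = TRUE)) / (1 + nNull)
  }, numeric(1))
  pbh <- p.adjust(p, method = "BH")
  result@pRaw <- p
  result@pBH <- pbh
  result@significantRaw <- p <= alpha
  result@significantBH <- pbh <= alpha
  result@alpha <- alpha
  validObject(result)
  result
}
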