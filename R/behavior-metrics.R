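#' @include accessors.R
NULL

#' Per-session acquisition metrics
#'
#' Total presses, percentage rewarded, response rate (presses per minute of
#' session), and a press-duration histogram as proportions over configured
#' bins (default: 10 equal bins from 0 to twice the criterion plus an
#' overflow bin).
#'
#' @param session a [BehavioralSession-class].
#' @param binEdgesMs histogram bin edges (ms); default
#'   `seq(0, 2 * criterion, length.out = 11)` plus `Inf`.
#' @return A list of class `SessionMetrics`: `sessionId`, `totalPresses`,
#'   `percentRewarded`, `responseRatePerMin`, `durationHistogram` (NULL when
#'   there are no presses), `binEdgesMs`.
#' @export
sessionMetrics <- function(session, binEdgesMs = NULL) {
  n <- nPresses(session)
  if (is.null(binEdgesMs))
    binEdgesMs <- c(seq(0, 2 * criterionMs(session), length.out = 11), Inf)
  minutes <- sessionEnd(session) / 60000
  if (n == 0) {
    return(structure(list(sessionId = sessionId(session), totalPresses = 0L,
                          percentRewarded = 0, responseRatePerMin = 0,
                          durationHistogram = NULL,
                          binEdgesMs = binEdgesMs),
                     class = "SessionMetrics"))
  }
  dur <- pressDurations(session)
  h <- table(cut(dur, binEdgesMs, right = FALSE))
  structure(list(
    sessionId = sessionId(session), totalPresses = n,
    percentRewarded = 100 * length(rewardTimes(session)) / n,
    responseRatePerMin = n / minutes,
    durationHistogram = as.numeric(h) / n,
    binEdgesMs = binEdgesMs), class = "SessionMetrics")
}

#' Devaluation-test response-rate normalization
#'
#' Normalizes a devaluation test-day response rate by the average response
#' rate of the mouse's last two criterion-1600 training sessions:
#' `rrTest / ((rrLast1 + rrLast2) / 2)`.
#'
#' @param rrTest test-day response rate.
#' @param rrLast1,rrLast2 response rates of the two baseline sessions.
#' @return The normalized rate (scale-invariant in the three inputs).
#' @export
devaluationNormalize <- function(rrTest, rrLast1, rrLast2) {
  stopifnot(rrTest >= 0, rrLast1 >= 0, rrLast2 >= 0)
  base <- (rrLast1 + rrLast2) / 2
  if (base <= 0) stopf("undefined normalization: zero baseline response rate")
  rrTest / base
}

#' Prefeeding consumption exclusion rule
#'
#' A mouse is excluded from devaluation analysis when it consumed too
#' little of the prefed outcome: strictly less than 0.1 g of pellets on the
#' devalued day or strictly less than 0.1 ml of sucrose on the valued day.
#'
#' @param pelletsG pellets consumed on the devalued day (g).
#' @param sucroseMl sucrose consumed on the valued day (ml).
#' @return List `(excluded, reason)`; `reason` is `NA` when included.
#' @export
prefeedExclusion <- function(pelletsG, sucroseMl) {
  if (pelletsG < 0 || sucroseMl < 0)
    stopf("validation error: negative consumption")
  if (pelletsG < 0.1)
    list(excluded = TRUE, reason = "pellets < 0.1 g on devalued day")
  else if (sucroseMl < 0.1)
    list(excluded = TRUE, reason = "sucrose < 0.1 ml on valued day")
  else list(excluded = FALSE, reason = NA_character_)
}

#' Chi-square comparison of two proportions
#'
#' Pearson chi-square on the 2x2 contingency table `k` out of `n` per
#' group, without continuity correction by default (switchable), df = 1.
#' Symmetric under swapping groups and under swapping outcome labels.
#'
#' @param k1,n1,k2,n2 successes and totals per group.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return A list of class `ProportionTest`: `counts` (2x2), `statistic`,
#'   `df`, `pValue`.
#' @export
compareProportions <- function(k1, n1, k2, n2, correct = FALSE) {
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2,
                dimnames = list(c("yes", "no"), c("g1", "g2")))
  if (any(tab < 0)) stopf("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("degenerate contingency table (zero margin)")
  ct <- chisq.test(tab, correct = correct)
  structure(list(counts = tab, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), pValue = ct$p.value),
            class = "ProportionTest")
}
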