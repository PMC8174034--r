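#' @include utils.R
NULL

#' Behavioral generative parameters
#'
#' Parameters of the synthetic self-paced session: presses alternate
#' exponential inter-press gaps with log-normal hold durations; reward
#' follows the strict-exceedance rule and the session terminates at
#' `maxRewards` rewards or `maxSessionMs`, whichever comes first.
#'
#' Defaults describe a late-training 1600-ms criterion session: median hold
#' ~1200 ms (`logDurationMu = log(1200)`), right-skewed spread
#' (`logDurationSigma = 0.6`, giving a ~32% success rate), ~8 s mean pause
#' between presses.
#'
#' @param criterionMs hold-duration criterion (ms).
#' @param logDurationMu,logDurationSigma log-normal hold-duration parameters
#'   (log-ms scale).
#' @param meanIpiMs mean exponential gap between a press offset and the next
#'   onset (ms).
#' @param maxRewards reward count terminating the session (default 60).
#' @param maxSessionMs hard session end (default 90 min).
#' @return A classed parameter list.
#' @export
behaviorParams <- function(criterionMs = 1600, logDurationMu = log(1200),
                           logDurationSigma = 0.6, meanIpiMs = 8000,
                           maxRewards = 60, maxSessionMs = 90 * 60 * 1000) {
  stopifnot(criterionMs > 0, logDurationSigma >= 0, meanIpiMs > 0,
            maxRewards >= 1, maxSessionMs > 0)
  structure(list(criterionMs = criterionMs, logDurationMu = logDurationMu,
                 logDurationSigma = logDurationSigma, meanIpiMs = meanIpiMs,
                 maxRewards = maxRewards, maxSessionMs = maxSessionMs),
            class = "BehaviorParams")
}

#' Event-anchored multiplicative gain kernel
#'
#' Gaussian gain bump (or dip) anchored to a task event. The unit's
#' instantaneous rate is multiplied by
#' `1 + (peakGain - 1) * max_e exp(-(t - e - latencyMs)^2 / (2 widthMs^2))`
#' where the max runs over the anchor's event times, so stacked events
#' saturate at `peakGain` rather than compounding (this keeps the thinning
#' bound exact).
#'
#' @param anchor `"press_onset"`, `"press_offset"` or `"reward"`.
#' @param latencyMs peak offset from the anchor event (ms; negative =
#'   anticipatory).
#' @param widthMs Gaussian SD (ms), positive.
#' @param peakGain multiplicative gain at the peak (>1 up-modulation,
#'   <1 down-modulation).
#' @return A classed parameter list.
#' @export
gainKernel <- function(anchor, latencyMs = 0, widthMs = 100, peakGain = 2) {
  stopifnot(anchor %in% EVENT_TYPES, widthMs > 0, peakGain >= 0)
  structure(list(anchor = anchor, latencyMs = latencyMs, widthMs = widthMs,
                 peakGain = peakGain), class = "GainKernel")
}

#' Hold-period suppression profile
#'
#' During each press the rate is multiplied by a U-profile: a constant
#' `depth` (in (0, 1]) over the hold with a multiplicative linear ramp from
#' 1 up to `prereleaseRampGain` over the final `rampFraction` of the press,
#' emulating the firing-rate climb toward lever release. `depthSlopePerS`
#' optionally deepens suppression with hold duration:
#' `effective depth = depth * exp(-depthSlopePerS * duration_s)`.
#'
#' @param depth suppression gain in (0, 1]; 0 is allowed and silences the
#'   unit during presses.
#' @param prereleaseRampGain terminal ramp gain (>= 1).
#' @param rampFraction fraction of the press duration occupied by the ramp.
#' @param depthSlopePerS duration-dependence of the depth (per second of
#'   hold; default 0 = duration-independent).
#' @return A classed parameter list.
#' @export
holdSuppression <- function(depth = 1, prereleaseRampGain = 1,
                            rampFraction = 0.25, depthSlopePerS = 0) {
  stopifnot(depth >= 0, depth <= 1, prereleaseRampGain >= 1,
            rampFraction >= 0, rampFraction <= 1, depthSlopePerS >= 0)
  structure(list(depth = depth, prereleaseRampGain = prereleaseRampGain,
                 rampFraction = rampFraction,
                 depthSlopePerS = depthSlopePerS), class = "HoldSuppression")
}

#' Single-unit generative parameters
#'
#' @param baseRateHz baseline Poisson rate (Hz).
#' @param kernels list of [gainKernel()] objects.
#' @param hold a [holdSuppression()] profile.
#' @param outcomeGainSuccess,outcomeGainFailure multiplicative gain applied
#'   in the (0, 1000] ms after a press offset, by press outcome.
#' @return A classed parameter list.
#' @export
unitParams <- function(baseRateHz = 8, kernels = list(),
                       hold = holdSuppression(),
                       outcomeGainSuccess = 1, outcomeGainFailure = 1) {
  stopifnot(baseRateHz > 0, is.finite(baseRateHz),
            outcomeGainSuccess >= 0, outcomeGainFailure >= 0)
  for (k in kernels) stopifnot(inherits(k, "GainKernel"))
  structure(list(baseRateHz = baseRateHz, kernels = kernels, hold = hold,
                 outcomeGainSuccess = outcomeGainSuccess,
                 outcomeGainFailure = outcomeGainFailure),
            class = "UnitParams")
}

#' Group-level gain multipliers
#'
#' Encodes treatment-group differences as multipliers on the unit gains:
#' `pressGainMultiplier` scales the peak gain of press-anchored kernels
#' (onset and offset); `outcomeGainMultiplier` scales reward-anchored kernel
#' gains and the post-offset outcome gains. The default CIE effect
#' (press x1.5, outcome x0.5) reproduces the direction of dependence-induced
#' changes: more press-related activity, less outcome-related activity.
#'
#' @param pressGainMultiplier,outcomeGainMultiplier positive multipliers.
#' @return A classed parameter list.
#' @export
groupEffect <- function(pressGainMultiplier = 1, outcomeGainMultiplier = 1) {
  stopifnot(pressGainMultiplier > 0, outcomeGainMultiplier > 0)
  structure(list(pressGainMultiplier = pressGainMultiplier,
                 outcomeGainMultiplier = outcomeGainMultiplier),
            class = "GroupEffect")
}

#' Default prior over unit parameters
#'
#' Specification of the distribution unit parameters are drawn from in
#' [simulateCohort()]. Baseline rates are log-normal around `medianRateHz`;
#' each unit receives an anticipatory press-onset kernel, a press-offset
#' kernel and a reward kernel with peak gains drawn uniformly from
#' `upGainRange` (down-modulated with probability `pDown`, peak drawn from
#' `downGainRange`); hold suppression and outcome gains are drawn from the
#' stated ranges. The study gives no quantitative firing-rate distributions,
#' so these are free parameters of the generator, not facts about the data.
#'
#' @param medianRateHz,rateSigmaLog log-normal baseline-rate parameters.
#' @param upGainRange,downGainRange peak-gain ranges for up/down kernels.
#' @param pDown probability a press-anchored kernel is down-modulated.
#' @param onsetLatencyRange,widthRange kernel latency/width ranges (ms).
#' @param holdDepthRange,rampGainRange hold-suppression ranges.
#' @param holdDepthSlopePerS duration slope of suppression (see
#'   [holdSuppression()]).
#' @param outcomeSuccessRange,outcomeFailureRange post-offset outcome gain
#'   ranges.
#' @return A classed prior list consumed by [simulateCohort()].
#' @export
unitPrior <- function(medianRateHz = 6, rateSigmaLog = 0.3,
                      upGainRange = c(1.6, 2.4), downGainRange = c(0.3, 0.7),
                      pDown = 0.3, onsetLatencyRange = c(-250, 50),
                      widthRange = c(80, 160),
                      holdDepthRange = c(0.5, 0.9),
                      rampGainRange = c(1.2, 1.8),
                      holdDepthSlopePerS = 0,
                      outcomeSuccessRange = c(1.6, 2.2),
                      outcomeFailureRange = c(0.8, 1.2)) {
  structure(as.list(environment()), class = "UnitPrior")
}

# Draw one UnitParams from a prior under the current RNG state.
sampleUnitParams <- function(prior) {
  drawGain <- function() {
    if (runif(1) < prior$pDown) runif(1, prior$downGainRange[1], prior$downGainRange[2])
    else runif(1, prior$upGainRange[1], prior$upGainRange[2])
  }
  kernels <- list(
    gainKernel("press_onset",
               latencyMs = runif(1, prior$onsetLatencyRange[1],
                                 prior$onsetLatencyRange[2]),
               widthMs = runif(1, prior$widthRange[1], prior$widthRange[2]),
               peakGain = drawGain()),
    gainKernel("press_offset",
               latencyMs = runif(1, 0, 150),
               widthMs = runif(1, prior$widthRange[1], prior$widthRange[2]),
               peakGain = drawGain()),
    gainKernel("reward",
               latencyMs = runif(1, 50, 300),
               widthMs = runif(1, prior$widthRange[1], prior$widthRange[2]),
               peakGain = runif(1, prior$upGainRange[1], prior$upGainRange[2]))
  )
  unitParams(
    baseRateHz = rlnorm(1, log(prior$medianRateHz), prior$rateSigmaLog),
    kernels = kernels,
    hold = holdSuppression(
      depth = runif(1, prior$holdDepthRange[1], prior$holdDepthRange[2]),
      prereleaseRampGain = runif(1, prior$rampGainRange[1],
                                 prior$rampGainRange[2]),
      rampFraction = 0.25, depthSlopePerS = prior$holdDepthSlopePerS),
    outcomeGainSuccess = runif(1, prior$outcomeSuccessRange[1],
                               prior$outcomeSuccessRange[2]),
    outcomeGainFailure = runif(1, prior$outcomeFailureRange[1],
                               prior$outcomeFailureRange[2]))
}
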