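#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Standard accessors for the package's S4 containers. Each returns the
#' corresponding slot or a value derived from it (e.g. `pressDurations` is
#' `pressOffsets - pressOnsets`).
#'
#' @param x an object of the relevant class.
#' @return The slot value (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))
#' @rdname accessors
#' @export
setGeneric("mouseId", function(x) standardGeneric("mouseId"))
#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setGeneric("criterionMs", function(x) standardGeneric("criterionMs"))
#' @rdname accessors
#' @export
setGeneric("pressOnsets", function(x) standardGeneric("pressOnsets"))
#' @rdname accessors
#' @export
setGeneric("pressOffsets", function(x) standardGeneric("pressOffsets"))
#' @rdname accessors
#' @export
setGeneric("pressDurations", function(x) standardGeneric("pressDurations"))
#' @rdname accessors
#' @export
setGeneric("rewardTimes", function(x) standardGeneric("rewardTimes"))
#' @rdname accessors
#' @export
setGeneric("sessionEnd", function(x) standardGeneric("sessionEnd"))
#' @rdname accessors
#' @export
setGeneric("pressOutcomes", function(x) standardGeneric("pressOutcomes"))
#' @rdname accessors
#' @export
setGeneric("nPresses", function(x) standardGeneric("nPresses"))
#' @rdname accessors
#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))
#' @rdname accessors
#' @export
setGeneric("sessions", function(x) standardGeneric("sessions"))
#' @rdname accessors
#' @export
setGeneric("units", function(x) standardGeneric("units"))
#' @rdname accessors
#' @export
setGeneric("rates", function(x) standardGeneric("rates"))
#' @rdname accessors
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))
#' @rdname accessors
#' @export
setGeneric("binLeftEdges", function(x) standardGeneric("binLeftEdges"))
#' @rdname accessors
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))
#' @rdname accessors
#' @export
setGeneric("eventType", function(x) standardGeneric("eventType"))
#' @rdname accessors
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))
#' @rdname accessors
#' @export
setGeneric("onsetLatency", function(x) standardGeneric("onsetLatency"))
#' @rdname accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setGeneric("timeCenters", function(x) standardGeneric("timeCenters"))

#' @rdname labelPressOutcomes
#' @export
setGeneric("labelPressOutcomes", function(x) standardGeneric("labelPressOutcomes"))
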