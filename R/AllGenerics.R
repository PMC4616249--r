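#' @name accessors
#' @title Accessors for operantVar data classes
#' @description Slot accessors; user code should use these rather than
#'   \code{@} access.
#' @param x an operantVar S4 object.
#' @return The slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("animalId", function(x) standardGeneric("animalId"))
#' @rdname accessors
#' @export
setGeneric("sessionIndex", function(x) standardGeneric("sessionIndex"))
#' @rdname accessors
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))
#' @rdname accessors
#' @export
setGeneric("pressTimes", function(x) standardGeneric("pressTimes"))
#' @rdname accessors
#' @export
setGeneric("headEntryTimes", function(x) standardGeneric("headEntryTimes"))
#' @rdname accessors
#' @export
setGeneric("reinforcerTimes", function(x) standardGeneric("reinforcerTimes"))
#' @rdname accessors
#' @export
setGeneric("sessionDuration", function(x) standardGeneric("sessionDuration"))
#' @rdname accessors
#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))
#' @rdname accessors
#' @export
setGeneric("region", function(x) standardGeneric("region"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("waveforms", function(x) standardGeneric("waveforms"))
#' @rdname accessors
#' @export
setGeneric("fanoValues", function(x) standardGeneric("fanoValues"))
#' @rdname accessors
#' @export
setGeneric("centerIndices", function(x) standardGeneric("centerIndices"))
#' @rdname accessors
#' @export
setGeneric("sessionIndices", function(x) standardGeneric("sessionIndices"))
#' @rdname accessors
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))
#' @rdname accessors
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setGeneric("rates", function(x) standardGeneric("rates"))
#' @rdname accessors
#' @export
setGeneric("baselineMean", function(x) standardGeneric("baselineMean"))
#' @rdname accessors
#' @export
setGeneric("baselineSd", function(x) standardGeneric("baselineSd"))
#' @rdname accessors
#' @export
setGeneric("modulation", function(x) standardGeneric("modulation"))

#' @rdname accessors
setMethod("animalId", "SessionEvents", function(x) x@animalId)
#' @rdname accessors
setMethod("sessionIndex", "SessionEvents", function(x) x@sessionIndex)
#' @rdname accessors
setMethod("schedule", "SessionEvents", function(x) x@schedule)
#' @rdname accessors
setMethod("pressTimes", "SessionEvents", function(x) x@pressTimes)
#' @rdname accessors
setMethod("headEntryTimes", "SessionEvents", function(x) x@headEntryTimes)
#' @rdname accessors
setMethod("reinforcerTimes", "SessionEvents", function(x) x@reinforcerTimes)
#' @rdname accessors
setMethod("sessionDuration", "SessionEvents", function(x) x@sessionDuration)
#' @rdname accessors
setMethod("unitId", "UnitRecording", function(x) x@unitId)
#' @rdname accessors
setMethod("region", "UnitRecording", function(x) x@region)
#' @rdname accessors
setMethod("spikeTimes", "UnitRecording", function(x) x@spikeTimes)
#' @rdname accessors
setMethod("waveforms", "UnitRecording", function(x) x@waveforms)
#' @rdname accessors
setMethod("fanoValues", "FanoTrace", function(x) x@values)
#' @rdname accessors
setMethod("centerIndices", "FanoTrace", function(x) x@centerIndices)
#' @rdname accessors
setMethod("sessionIndices", "FanoTrace", function(x) x@sessionIndices)
#' @rdname accessors
setMethod("windowSize", "FanoTrace", function(x) x@windowSize)
#' @rdname accessors
setMethod("binCenters", "PETHProfile", function(x) x@binCenters)
#' @rdname accessors
setMethod("rates", "PETHProfile", function(x) x@rates)
#' @rdname accessors
setMethod("baselineMean", "PETHProfile", function(x) x@baselineMean)
#' @rdname accessors
setMethod("baselineSd", "PETHProfile", function(x) x@baselineSd)
#' @rdname accessors
setMethod("modulation", "PETHProfile", function(x) x@modulation)
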