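#' @import methods
#' @import stats
#' @importFrom utils read.csv write.csv write.table head tail
#' @importFrom graphics hist
NULL

.REGIONS <- c("M1", "DS")
.SCHEDULE_MODES <- c("frequency_target", "count_target",
                     "continuous_reinforcement")

#' Reinforcement schedule for one training session
#'
#' A schedule is one of three modes: \code{frequency_target} (reinforce a
#' sequence once three consecutive inter-press intervals sum below
#' \code{summedIpiBound} = 3 / \code{targetFrequency}), \code{count_target}
#' (reinforce bouts of exactly \code{requiredCount} presses), or
#' \code{continuous_reinforcement} (every press reinforced).
#' A \code{targetFrequency} of 0 encodes a free session with no minimum
#' frequency: any three consecutive intervals qualify (bound = Inf).
#'
#' @slot mode character; one of \code{"frequency_target"},
#'   \code{"count_target"}, \code{"continuous_reinforcement"}.
#' @slot targetFrequency numeric; covert minimum frequency in Hz
#'   (0 = no minimum), \code{NA} for non-frequency modes.
#' @slot summedIpiBound numeric; bound in seconds on the sum of three
#'   consecutive inter-press intervals, equal to 3 / targetFrequency.
#' @slot requiredCount integer; exact press count for \code{count_target}.
#' @export
setClass("ScheduleEntry",
  representation(mode = "character", targetFrequency = "numeric",
                 summedIpiBound = "numeric", requiredCount = "integer"),
  prototype(mode = "frequency_target", targetFrequency = 4.5,
            summedIpiBound = 3 / 4.5, requiredCount = NA_integer_))

setValidity("ScheduleEntry", function(object) {
  msg <- character()
  if (length(object@mode) != 1L || !object@mode %in% .SCHEDULE_MODES)
    msg <- c(msg, sprintf("mode must be one of %s",
                          paste(.SCHEDULE_MODES, collapse = ", ")))
  else if (object@mode == "frequency_target") {
    f <- object@targetFrequency
    if (length(f) != 1L || is.na(f) || f < 0)
      msg <- c(msg, "frequency_target mode requires targetFrequency >= 0")
    else {
      want <- if (f > 0) 3 / f else Inf
      b <- object@summedIpiBound
      ok <- if (is.finite(want)) isTRUE(abs(b - want) < 1e-9) else is.infinite(b)
      if (!ok)
        msg <- c(msg, "summedIpiBound must equal 3 / targetFrequency")
    }
  } else if (object@mode == "count_target") {
    if (is.na(object@requiredCount) || object@requiredCount < 2L)
      msg <- c(msg, "count_target mode requires requiredCount >= 2")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ScheduleEntry
#'
#' @param mode schedule mode; see \linkS4class{ScheduleEntry}.
#' @param targetFrequency covert minimum frequency in Hz (0 = free session).
#' @param requiredCount exact press count for the count-target control task.
#' @return A \linkS4class{ScheduleEntry}.
#' @examples
#' scheduleEntry(targetFrequency = 4.5)  # final covert target, 3 IPIs < 660 ms
#' scheduleEntry("count_target", requiredCount = 4)
#' @export
scheduleEntry <- function(mode = "frequency_target", targetFrequency = NA_real_,
                          requiredCount = NA_integer_) {
  mode <- match.arg(mode, .SCHEDULE_MODES)
  bound <- NA_real_
  if (mode == "frequency_target") {
    if (is.na(targetFrequency))
      stop("frequency_target mode requires targetFrequency")
    bound <- if (targetFrequency > 0) 3 / targetFrequency else Inf
  }
  new("ScheduleEntry", mode = mode,
      targetFrequency = as.numeric(targetFrequency),
      summedIpiBound = bound,
      requiredCount = as.integer(requiredCount))
}

#' Timestamped events of one operant session
#'
#' Holds the raw behavioral record of a single training session: lever-press,
#' magazine head-entry, and reinforcer-delivery times, all in seconds from
#' session start, plus the reinforcement schedule in force.
#'
#' @slot animalId character scalar.
#' @slot sessionIndex integer; 1-based position in the training order.
#' @slot schedule a \linkS4class{ScheduleEntry}.
#' @slot pressTimes strictly increasing numeric vector, seconds.
#' @slot headEntryTimes increasing numeric vector, seconds.
#' @slot reinforcerTimes increasing numeric vector, seconds.
#' @slot sessionDuration numeric scalar, seconds.
#' @export
setClass("SessionEvents",
  representation(animalId = "character", sessionIndex = "integer",
                 schedule = "ScheduleEntry", pressTimes = "numeric",
                 headEntryTimes = "numeric", reinforcerTimes = "numeric",
                 sessionDuration = "numeric"))

setValidity("SessionEvents", function(object) {
  msg <- character()
  d <- object@sessionDuration
  if (length(d) != 1L || is.na(d) || d <= 0)
    msg <- c(msg, "sessionDuration must be a positive scalar")
  for (nm in c("pressTimes", "headEntryTimes", "reinforcerTimes")) {
    tt <- slot(object, nm)
    if (anyNA(tt)) msg <- c(msg, sprintf("%s contains NA", nm))
    else {
      if (length(tt) && (min(tt) < 0 || (length(d) == 1L && !is.na(d) &&
                                         max(tt) > d)))
        msg <- c(msg, sprintf("%s outside [0, sessionDuration]", nm))
      if (is.unsorted(tt, strictly = (nm == "pressTimes")))
        msg <- c(msg, sprintf("%s must be %sincreasing", nm,
                              if (nm == "pressTimes") "strictly " else ""))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SessionEvents object
#'
#' @param animalId animal identifier.
#' @param sessionIndex 1-based session order.
#' @param schedule a \linkS4class{ScheduleEntry}.
#' @param pressTimes,headEntryTimes,reinforcerTimes event times in seconds.
#' @param sessionDuration session length in seconds.
#' @return A \linkS4class{SessionEvents}.
#' @export
sessionEvents <- function(animalId, sessionIndex, schedule,
                          pressTimes = numeric(), headEntryTimes = numeric(),
                          reinforcerTimes = numeric(), sessionDuration) {
  new("SessionEvents", animalId = as.character(animalId),
      sessionIndex = as.integer(sessionIndex), schedule = schedule,
      pressTimes = as.numeric(pressTimes),
      headEntryTimes = as.numeric(headEntryTimes),
      reinforcerTimes = as.numeric(reinforcerTimes),
      sessionDuration = as.numeric(sessionDuration))
}

#' Spike record of one sorted unit across sessions
#'
#' @slot unitId character scalar.
#' @slot region \code{"M1"} (motor cortex layer 5) or \code{"DS"}
#'   (dorsal striatum).
#' @slot spikeTimes named list (names = session index) of strictly
#'   increasing spike-time vectors, seconds.
#' @slot waveforms named list of numeric matrices, one row per spike
#'   snippet; all matrices of one unit share the same column count.
#' @export
setClass("UnitRecording",
  representation(unitId = "character", region = "character",
                 spikeTimes = "list", waveforms = "list"))

setValidity("UnitRecording", function(object) {
  msg <- character()
  if (!object@region %in% .REGIONS)
    msg <- c(msg, "region must be 'M1' or 'DS'")
  for (s in names(object@spikeTimes)) {
    tt <- object@spikeTimes[[s]]
    if (is.unsorted(tt, strictly = TRUE))
      msg <- c(msg, sprintf("spikeTimes in session %s not strictly increasing", s))
  }
  ncols <- unique(vapply(object@waveforms, ncol, 1L))
  if (length(ncols) > 1L)
    msg <- c(msg, "waveform matrices must share one snippet width")
  if (length(msg)) msg else TRUE
})

#' Construct a UnitRecording
#'
#' @param unitId unit identifier.
#' @param region \code{"M1"} or \code{"DS"}.
#' @param spikeTimes named list of spike-time vectors by session index.
#' @param waveforms named list of snippet matrices by session index.
#' @return A \linkS4class{UnitRecording}.
#' @export
unitRecording <- function(unitId, region, spikeTimes, waveforms = list()) {
  new("UnitRecording", unitId = as.character(unitId),
      region = as.character(region), spikeTimes = spikeTimes,
      waveforms = waveforms)
}

#' Sliding-window Fano-factor trace
#'
#' Fano factors of a feature (behavioral or neural) computed in a moving
#' window of \code{windowSize} consecutive trials shifted by one trial;
#' windows never span session boundaries.
#'
#' @slot windowSize odd integer window length in trials (3, 5 or 7).
#' @slot values numeric Fano factors, one per window.
#' @slot centerIndices integer global trial index at each window center.
#' @slot sessionIndices integer session of each window.
#' @export
setClass("FanoTrace",
  representation(windowSize = "integer", values = "numeric",
                 centerIndices = "integer", sessionIndices = "integer"))

setValidity("FanoTrace", function(object) {
  msg <- character()
  if (object@windowSize < 3L || object@windowSize %% 2L == 0L)
    msg <- c(msg, "windowSize must be an odd integer >= 3")
  n <- length(object@values)
  if (length(object@centerIndices) != n || length(object@sessionIndices) != n)
    msg <- c(msg, "values, centerIndices, sessionIndices must align")
  if (any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "Fano factors must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Peri-event time histogram of one unit
#'
#' Trial-averaged firing rate in overlapping 20-ms bins stepped by 1 ms,
#' aligned to a behavioral event (the first press of each sequence), with
#' baseline statistics from the \eqn{[-5, -2)} s pre-press region and a
#' modulation label from the consecutive-bin rule.
#'
#' @slot binCenters seconds relative to the alignment event.
#' @slot rates Hz per bin, averaged across trials.
#' @slot binWidth,binStep seconds (defaults 0.020 and 0.001).
#' @slot nTrials number of trials averaged.
#' @slot baselineMean,baselineSd Hz, over baseline-region bins.
#' @slot modulation \code{"positive"}, \code{"negative"} or \code{"none"}.
#' @slot sequenceRelated logical; paired-test call (NA when untested).
#' @export
setClass("PETHProfile",
  representation(binCenters = "numeric", rates = "numeric",
                 binWidth = "numeric", binStep = "numeric",
                 nTrials = "integer", baselineMean = "numeric",
                 baselineSd = "numeric", modulation = "character",
                 sequenceRelated = "logical"),
  prototype(modulation = "none", sequenceRelated = NA))

setValidity("PETHProfile", function(object) {
  msg <- character()
  if (length(object@rates) != length(object@binCenters))
    msg <- c(msg, "rates and binCenters must align")
  if (any(object@rates < 0)) msg <- c(msg, "rates must be non-negative")
  if (!object@modulation %in% c("positive", "negative", "none"))
    msg <- c(msg, "modulation must be positive/negative/none")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScheduleEntry", function(object) {
  cat("ScheduleEntry:", object@mode)
  if (object@mode == "frequency_target")
    cat(sprintf(" (target %.3g Hz, sum of 3 IPIs < %.3g s)",
                object@targetFrequency, object@summedIpiBound))
  if (object@mode == "count_target")
    cat(sprintf(" (exactly %d presses)", object@requiredCount))
  cat("\n")
})

setMethod("show", "SessionEvents", function(object) {
  cat(sprintf("SessionEvents: animal %s, session %d (%.0f s)\n",
              object@animalId, object@sessionIndex, object@sessionDuration))
  cat(sprintf("  %d presses, %d head entries, %d reinforcers\n",
              length(object@pressTimes), length(object@headEntryTimes),
              length(object@reinforcerTimes)))
  show(object@schedule)
})

setMethod("show", "UnitRecording", function(object) {
  cat(sprintf("UnitRecording: %s [%s], %d session(s), %d spikes total\n",
              object@unitId, object@region, length(object@spikeTimes),
              sum(lengths(object@spikeTimes))))
})

setMethod("show", "FanoTrace", function(object) {
  cat(sprintf("FanoTrace: window %d trials, %d windows over %d session(s)\n",
              object@windowSize, length(object@values),
              length(unique(object@sessionIndices))))
})

setMethod("show", "PETHProfile", function(object) {
  cat(sprintf(
    "PETHProfile: %d bins (%.0f-ms width, %.0f-ms step), %d trials\n",
    length(object@rates), object@binWidth * 1000, object@binStep * 1000,
    object@nTrials))
  cat(sprintf("  baseline %.2f +/- %.2f Hz, modulation: %s\n",
              object@baselineMean, object@baselineSd, object@modulation))
})
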