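## Sequence (bout) segmentation and the covert-frequency-target logic.
## A sequence is a run of >= 2 presses with no inter-press interval (IPI)
## above the gap threshold (2 s, the valley of the IPI distribution) and no
## magazine head entry between presses. The covert target is met when three
## consecutive IPIs sum below 3 / target frequency (660 ms at 4.5 Hz).

#' Segment a press stream into sequences and isolated presses
#'
#' A boundary falls between consecutive presses when their interval exceeds
#' \code{gapThreshold} or at least one head entry lies strictly between
#' them. Runs of two or more presses become sequences; single presses are
#' counted separately.
#'
#' @param pressTimes sorted press times, seconds.
#' @param headEntryTimes sorted head-entry times, seconds.
#' @param gapThreshold boundary IPI in seconds (default 2).
#' @return List with \code{sequences} (list of press-time vectors, each of
#'   length >= 2) and \code{isolatedCount}.
#' @examples
#' segmentSequences(c(0, 0.3, 0.6, 3.6, 3.9))
#' @export
segmentSequences <- function(pressTimes, headEntryTimes = numeric(),
                             gapThreshold = 2.0) {
  if (is.unsorted(pressTimes) || is.unsorted(headEntryTimes))
    stop("press and head-entry times must be sorted ascending")
  n <- length(pressTimes)
  if (n == 0L)
    return(list(sequences = list(), isolatedCount = 0L))
  split <- logical(n - 1L)
  if (n > 1L) {
    gaps <- diff(pressTimes)
    split <- gaps > gapThreshold
    if (length(headEntryTimes)) {
      # a head entry strictly inside (p_i, p_{i+1}) also breaks the bout
      lo <- findInterval(headEntryTimes, pressTimes)
      idx <- which(lo >= 1L & lo < n)
      ins <- idx[headEntryTimes[idx] > pressTimes[lo[idx]] &
                 headEntryTimes[idx] < pressTimes[lo[idx] + 1L]]
      split[unique(lo[ins])] <- TRUE
    }
  }
  runId <- cumsum(c(1L, as.integer(split)))
  runs <- unname(split(pressTimes, runId))
  keep <- lengths(runs) >= 2L
  list(sequences = runs[keep], isolatedCount = sum(!keep))
}

#' Per-sequence features: frequency, duration, length
#'
#' Frequency is the inverse of the mean IPI; duration the time from first
#' to last press; length the press count.
#'
#' @param pressTimes press times of one sequence (length >= 2).
#' @return List with \code{frequency} (Hz), \code{duration} (s),
#'   \code{length} (count).
#' @examples
#' sequenceFeatures(c(0, 0.2, 0.4, 0.8))  # 3.75 Hz, 0.8 s, 4 presses
#' @export
sequenceFeatures <- function(pressTimes) {
  if (length(pressTimes) < 2L)
    stop("sequence features are undefined for fewer than 2 presses")
  ipis <- diff(pressTimes)
  list(frequency = 1 / mean(ipis),
       duration = pressTimes[length(pressTimes)] - pressTimes[1L],
       length = length(pressTimes))
}

#' Scan inter-press intervals for covert-target hits
#'
#' Scans left to right for windows of three consecutive IPIs whose sum is
#' strictly below \code{summedIpiBound}; a hit fires at the press completing
#' the window (1-based press index = IPI index + 3). With
#' \code{resetOnHit = TRUE} (the online reinforcement rule) IPIs are not
#' reused across hits; with \code{FALSE} every stride-1 window is tested
#' (the analysis-side rule).
#'
#' @param ipis inter-press intervals, seconds.
#' @param summedIpiBound bound on the 3-IPI sum, seconds (660 ms for the
#'   4.5-Hz end target); \code{Inf} means any triple qualifies.
#' @param resetOnHit logical, see above.
#' @return Integer vector of hit press indices (possibly empty).
#' @examples
#' detectCovertTargets(c(0.2, 0.2, 0.2, 0.5), 0.660)     # press 4
#' detectCovertTargets(rep(0.1, 7), 0.660)               # presses 4, 7
#' detectCovertTargets(rep(0.1, 7), 0.660, resetOnHit = FALSE)
#' @export
detectCovertTargets <- function(ipis, summedIpiBound, resetOnHit = TRUE) {
  if (summedIpiBound <= 0) stop("summedIpiBound must be positive")
  n <- length(ipis)
  if (n < 3L) return(integer())
  hits <- integer()
  if (resetOnHit) {
    i <- 1L
    while (i + 2L <= n) {
      if (sum(ipis[i:(i + 2L)]) < summedIpiBound) {
        hits <- c(hits, i + 3L)
        i <- i + 3L
      } else i <- i + 1L
    }
  } else {
    sums <- ipis[1:(n - 2L)] + ipis[2:(n - 1L)] + ipis[3:n]
    hits <- which(sums < summedIpiBound) + 3L
  }
  hits
}

#' Label sequences with reinforcement outcomes
#'
#' Applies the schedule rule to segmented sequences: a frequency-target
#' sequence is reinforced when it contains at least one covert-target hit
#' (online rule, window reset after each hit); a count-target sequence when
#' its length equals the required count; under continuous reinforcement
#' every sequence is reinforced.
#'
#' @param sequences list of press-time vectors from
#'   \code{\link{segmentSequences}}.
#' @param schedule a \linkS4class{ScheduleEntry}.
#' @return List with \code{reinforced} (logical per sequence) and
#'   \code{hitIndices} (list of within-sequence press indices completing a
#'   hit; reinforcers are delivered at these presses).
#' @export
labelReinforcement <- function(sequences, schedule) {
  validObject(schedule)
  mode <- schedule@mode
  hitIdx <- vector("list", length(sequences))
  reinforced <- logical(length(sequences))
  for (i in seq_along(sequences)) {
    p <- sequences[[i]]
    hits <- integer()
    if (mode == "frequency_target") {
      hits <- detectCovertTargets(diff(p), schedule@summedIpiBound,
                                  resetOnHit = TRUE)
      reinforced[i] <- length(hits) > 0L
    } else if (mode == "count_target") {
      reinforced[i] <- length(p) == schedule@requiredCount
      if (reinforced[i]) hits <- length(p)
    } else {
      reinforced[i] <- TRUE
      hits <- seq_along(p)
    }
    hitIdx[[i]] <- hits
  }
  list(reinforced = reinforced, hitIndices = hitIdx)
}

#' Sequence table for one session
#'
#' Segments and labels one session, returning one row per sequence with the
#' press times attached as an attribute.
#'
#' @param events a \linkS4class{SessionEvents}.
#' @param gapThreshold boundary IPI, seconds.
#' @return data.frame with columns animal, session, start_s, length,
#'   frequency_hz, duration_s, reinforced, n_hits; attributes
#'   \code{pressTimes} (list), \code{hitIndices} (list),
#'   \code{isolatedCount}.
#' @export
sessionSequences <- function(events, gapThreshold = 2.0) {
  seg <- segmentSequences(pressTimes(events), headEntryTimes(events),
                          gapThreshold)
  lab <- labelReinforcement(seg$sequences, schedule(events))
  feats <- lapply(seg$sequences, sequenceFeatures)
  n <- length(seg$sequences)
  tab <- data.frame(
    animal = rep(animalId(events), n),
    session = rep(sessionIndex(events), n),
    start_s = vapply(seg$sequences, function(p) p[1L], 1, USE.NAMES = FALSE),
    length = vapply(feats, function(f) as.integer(f$length), 1L),
    frequency_hz = vapply(feats, `[[`, 1, "frequency"),
    duration_s = vapply(feats, `[[`, 1, "duration"),
    reinforced = lab$reinforced,
    n_hits = lengths(lab$hitIndices))
  attr(tab, "pressTimes") <- seg$sequences
  attr(tab, "hitIndices") <- lab$hitIndices
  attr(tab, "isolatedCount") <- seg$isolatedCount
  tab
}

.threeIpiWindowSums <- function(sequences) {
  # stride-1 windows of 3 consecutive IPIs, never spanning sequences
  unlist(lapply(sequences, function(p) {
    ipis <- diff(p)
    n <- length(ipis)
    if (n < 3L) return(numeric())
    ipis[1:(n - 2L)] + ipis[2:(n - 1L)] + ipis[3:n]
  }), use.names = FALSE)
}

#' Session-level behavioral summary
#'
#' Computes the per-session statistics used to track shaping toward the
#' final covert target: press and sequence rates, the share of presses
#' organized in sequences, reinforcement rate, the mean signed distance of
#' all 3-IPI window sums from the end-target bound, the RMS spread of those
#' sums around the bound, the share of sequences containing the end target,
#' and magazine-check probabilities.
#'
#' @param events a \linkS4class{SessionEvents}.
#' @param endTargetBound final covert-target bound on the 3-IPI sum,
#'   seconds (default 0.660, i.e. 4.5 Hz).
#' @param gapThreshold boundary IPI, seconds.
#' @return One-row data.frame; distance/spread are \code{NA} when the
#'   session has no 3-IPI window.
#' @export
sessionSummary <- function(events, endTargetBound = 0.660,
                           gapThreshold = 2.0) {
  tab <- sessionSequences(events, gapThreshold)
  seqs <- attr(tab, "pressTimes")
  nPress <- length(pressTimes(events))
  inSeq <- sum(lengths(seqs))
  minutes <- sessionDuration(events) / 60
  sums <- .threeIpiWindowSums(seqs)
  hitEnd <- vapply(seqs, function(p)
    length(detectCovertTargets(diff(p), endTargetBound)) > 0L, TRUE,
    USE.NAMES = FALSE)
  checks <- magazineCheckProbabilities(events, tab)
  data.frame(
    animal = animalId(events),
    session = sessionIndex(events),
    n_presses = nPress,
    n_sequences = length(seqs),
    isolated_presses = attr(tab, "isolatedCount"),
    presses_per_min = nPress / minutes,
    sequences_per_min = length(seqs) / minutes,
    pct_presses_in_sequences = if (nPress) 100 * inSeq / nPress else NA_real_,
    pct_reinforced_sequences = if (length(seqs))
      100 * mean(tab$reinforced) else NA_real_,
    distance_to_end_target = if (length(sums))
      mean(sums - endTargetBound) else NA_real_,
    spread_around_end_target = if (length(sums))
      sqrt(mean((sums - endTargetBound)^2)) else NA_real_,
    pct_sequences_hitting_end_target = if (length(seqs))
      100 * mean(hitEnd) else NA_real_,
    p_check_after_success = checks$afterSuccess,
    p_check_after_reinforced_press = checks$afterReinforcedPress,
    p_check_after_nonreinforced_press = checks$afterNonReinforcedPress)
}

#' Probability of a magazine check after a press
#'
#' For each conditioning set of presses, the probability that the next
#' recorded animal action (press or head entry; reinforcer delivery is not
#' an animal action) is a head entry. Conditioning sets: presses completing
#' a covert-target hit ("success"), reinforced presses, and non-reinforced
#' presses.
#'
#' @param events a \linkS4class{SessionEvents}.
#' @param seqTable optional precomputed \code{\link{sessionSequences}}
#'   table.
#' @param gapThreshold boundary IPI, seconds.
#' @return List with \code{afterSuccess}, \code{afterReinforcedPress},
#'   \code{afterNonReinforcedPress}; \code{NA} when a set is empty.
#' @export
magazineCheckProbabilities <- function(events, seqTable = NULL,
                                       gapThreshold = 2.0) {
  if (is.null(seqTable)) seqTable <- sessionSequences(events, gapThreshold)
  seqs <- attr(seqTable, "pressTimes")
  hitIdx <- attr(seqTable, "hitIndices")
  hitPressTimes <- unlist(Map(function(p, h) p[h], seqs, hitIdx),
                          use.names = FALSE)
  press <- pressTimes(events)
  he <- headEntryTimes(events)
  nextIsHeadEntry <- function(t) {
    nextPress <- press[press > t]
    nextHe <- he[he > t]
    if (!length(nextHe)) return(FALSE)
    if (!length(nextPress)) return(TRUE)
    nextHe[1L] < nextPress[1L]
  }
  prob <- function(times) {
    if (!length(times)) return(NA_real_)
    mean(vapply(times, nextIsHeadEntry, TRUE))
  }
  reinforcedPress <- hitPressTimes
  nonReinforced <- setdiff(press, reinforcedPress)
  list(afterSuccess = prob(hitPressTimes),
       afterReinforcedPress = prob(reinforcedPress),
       afterNonReinforcedPress = prob(nonReinforced))
}
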