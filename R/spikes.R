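## Trial-aligned firing rates, Fano factors, modulation ratios, PETHs and
## task-relatedness classification. All windows are half-open [a, b).

#' Firing rate in a half-open window
#'
#' @param spikeTimes sorted spike times, seconds.
#' @param window numeric length-2 \code{c(a, b)} with \code{b > a}; spikes
#'   in \code{[a, b)} are counted.
#' @return Rate in Hz.
#' @examples
#' windowRate(c(1, 1.5, 2), c(1, 2))  # 2 Hz: spike at 2.0 excluded
#' @export
windowRate <- function(spikeTimes, window) {
  if (length(window) != 2L || !(window[2L] > window[1L]))
    stop("window must be c(a, b) with b > a")
  .windowCount(spikeTimes, window[1L], window[2L]) / (window[2L] - window[1L])
}

.windowCount <- function(spikeTimes, a, b) {
  # count of spikes in [a, b) for sorted input
  sum(spikeTimes >= a & spikeTimes < b)
}

#' Trial windows for sequence-aligned neural analysis
#'
#' For each sequence: the sequence window \code{[first, last)} press, the
#' baseline window \code{[first - 5, first - 2)}, and 1-s flank windows
#' centered on the first and last press. Trials whose baseline window would
#' start before the session are dropped, not truncated.
#'
#' @param seqTable sequence table for one session (needs columns
#'   \code{start_s}, \code{duration_s}).
#' @param baselineOffset numeric length-2: baseline window start/end
#'   relative to the first press (default \code{c(-5, -2)}).
#' @return data.frame with seq_start, seq_end, base_start, base_end,
#'   first_flank_start/end, last_flank_start/end; one row per kept trial.
#' @export
trialWindows <- function(seqTable, baselineOffset = c(-5, -2)) {
  first <- seqTable$start_s
  last <- seqTable$start_s + seqTable$duration_s
  keep <- first + baselineOffset[1L] >= 0
  first <- first[keep]; last <- last[keep]
  data.frame(
    seq_start = first, seq_end = last,
    base_start = first + baselineOffset[1L],
    base_end = first + baselineOffset[2L],
    first_flank_start = first - 0.5, first_flank_end = first + 0.5,
    last_flank_start = last - 0.5, last_flank_end = last + 0.5)
}

#' Fano factor of per-trial firing rates
#'
#' Variance of firing rates across all trials of a session divided by their
#' mean.
#'
#' @param rates Hz, one value per trial (n >= 2).
#' @return Fano factor, or \code{NA} when the mean rate is 0.
#' @export
unitFanoAcrossTrials <- function(rates) {
  if (length(rates) < 2L)
    stop("Fano factor across trials requires at least 2 trials")
  m <- mean(rates)
  if (m <= 0) return(NA_real_)
  stats::var(rates) / m
}

#' Sequence-vs-baseline modulation ratio
#'
#' \code{(sequence - baseline) / baseline}, applied to Fano factors and to
#' firing rates.
#'
#' @param valueSequence,valueBaseline scalars; baseline must be > 0 for a
#'   defined ratio.
#' @return The ratio, or \code{NA} when baseline is not positive.
#' @export
modulationRatio <- function(valueSequence, valueBaseline) {
  if (is.na(valueBaseline) || valueBaseline <= 0) return(NA_real_)
  (valueSequence - valueBaseline) / valueBaseline
}

#' Build a peri-event time histogram
#'
#' Spike counts in 20-ms bins shifted by 1 ms, averaged across trials and
#' scaled to Hz. Baseline statistics are taken over bins whose centers lie
#' in \code{[-5, -2)} s relative to the alignment event.
#'
#' @param spikeTimesPerTrial list of sorted spike-time vectors (absolute
#'   session time), one per trial.
#' @param alignTimes alignment event time per trial (first press of each
#'   sequence), same length as the trial list.
#' @param range PETH extent in seconds relative to alignment
#'   (default \code{c(-5, 2)}).
#' @param binWidth,binStep bin parameters in seconds (defaults 0.020,
#'   0.001).
#' @return A \linkS4class{PETHProfile} (modulation label unset; see
#'   \code{\link{classifyTaskRelated}}).
#' @export
buildPETH <- function(spikeTimesPerTrial, alignTimes, range = c(-5, 2),
                      binWidth = 0.020, binStep = 0.001) {
  nTrials <- length(alignTimes)
  if (nTrials < 1L) stop("PETH requires at least one trial")
  stopifnot(length(spikeTimesPerTrial) == nTrials)
  # pool relative spike times, count on the fine binStep grid, then take a
  # running sum over binWidth/binStep fine cells
  rel <- unlist(Map(function(st, t0) st - t0, spikeTimesPerTrial, alignTimes),
                use.names = FALSE)
  k <- round(binWidth / binStep)
  centers <- seq(range[1L] + binWidth / 2, range[2L] - binWidth / 2,
                 by = binStep)
  centers <- round(centers, 9)
  fineEdges <- seq(range[1L], range[2L], by = binStep)
  nFine <- length(fineEdges) - 1L
  counts <- integer(nFine)
  if (length(rel)) {
    rel <- rel[rel >= range[1L] & rel < range[2L]]
    cell <- floor((rel - range[1L]) / binStep) + 1L
    cell[cell > nFine] <- nFine
    tb <- tabulate(cell, nbins = nFine)
    counts <- tb
  }
  cs <- c(0L, cumsum(counts))
  # window [i, i + k): counts in fine cells i .. i+k-1
  nBins <- nFine - k + 1L
  binCounts <- cs[(k + 1L):(nFine + 1L)] - cs[1:nBins]
  rate <- binCounts / (nTrials * binWidth)
  stopifnot(length(rate) == length(centers))
  baseIdx <- centers >= -5 & centers < -2
  bm <- if (any(baseIdx)) mean(rate[baseIdx]) else NA_real_
  bs <- if (sum(baseIdx) >= 2L) stats::sd(rate[baseIdx]) else NA_real_
  new("PETHProfile", binCenters = centers, rates = rate,
      binWidth = binWidth, binStep = binStep, nTrials = as.integer(nTrials),
      baselineMean = bm, baselineSd = bs,
      modulation = "none", sequenceRelated = NA)
}

.longestRun <- function(flags) {
  if (!length(flags) || !any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

#' Classify a unit as task-related from its PETH
#'
#' Positive modulation: at least \code{minRun} consecutive bins outside the
#' baseline region above the upper baseline threshold; negative: at least
#' \code{minRun} consecutive bins below the lower threshold. The default
#' \code{thresholdMethod = "relative"} reads "99\% above" / "95\% below"
#' baseline activity as proportions of the baseline mean rate: upper
#' threshold = 1.99 x baseline mean, lower = 0.05 x baseline mean (a
#' near-silencing bound). Alternatives: \code{"percentile"} (99th / 5th
#' empirical percentiles of baseline-region bin rates; note that with
#' heavily overlapping bins flat units frequently dip below a 5th
#' percentile for 20 consecutive 1-ms shifts, so this reading mislabels
#' null units) and \code{"zscore"} (baseline mean + 2.326 SD / - 1.645
#' SD). When both rules fire, the longer excursion wins.
#' Sequence-relatedness is a paired t-test between per-trial baseline and
#' sequence firing rates.
#'
#' @param peth a \linkS4class{PETHProfile}.
#' @param sequenceRates,baselineRates per-trial rates (Hz), paired by
#'   trial; may be NULL to skip the paired test.
#' @param alpha significance level for the paired test.
#' @param minRun minimum consecutive-bin run (default 20).
#' @param thresholdMethod \code{"relative"}, \code{"percentile"} or
#'   \code{"zscore"}.
#' @return The PETH with \code{modulation} and \code{sequenceRelated} set.
#' @export
classifyTaskRelated <- function(peth, sequenceRates = NULL,
                                baselineRates = NULL, alpha = 0.05,
                                minRun = 20L,
                                thresholdMethod = c("relative",
                                                    "percentile",
                                                    "zscore")) {
  thresholdMethod <- match.arg(thresholdMethod)
  centers <- binCenters(peth)
  r <- rates(peth)
  baseIdx <- centers >= -5 & centers < -2
  if (!any(baseIdx)) stop("baseline region empty")
  base <- r[baseIdx]
  if (thresholdMethod == "relative") {
    up <- mean(base) * (1 + 0.99)
    lo <- mean(base) * (1 - 0.95)
  } else if (thresholdMethod == "percentile") {
    up <- stats::quantile(base, 0.99, names = FALSE)
    lo <- stats::quantile(base, 0.05, names = FALSE)
  } else {
    up <- mean(base) + stats::qnorm(0.99) * stats::sd(base)
    lo <- mean(base) - stats::qnorm(0.95) * stats::sd(base)
  }
  out <- r[!baseIdx]
  runUp <- .longestRun(out > up)
  runDown <- .longestRun(out < lo)
  label <- "none"
  if (runUp >= minRun && runDown >= minRun)
    label <- if (runUp >= runDown) "positive" else "negative"
  else if (runUp >= minRun) label <- "positive"
  else if (runDown >= minRun) label <- "negative"
  seqRel <- NA
  if (!is.null(sequenceRates) && !is.null(baselineRates) &&
      length(sequenceRates) >= 2L &&
      length(sequenceRates) == length(baselineRates) &&
      stats::sd(sequenceRates - baselineRates) > 0) {
    p <- stats::t.test(sequenceRates, baselineRates, paired = TRUE)$p.value
    seqRel <- p < alpha
  }
  initialize(peth, modulation = label, sequenceRelated = seqRel)
}

#' Per-unit, per-session firing statistics and modulation ratios
#'
#' For one unit and one session's sequence table: per-trial sequence and
#' baseline rates, their means, Fano factors across trials, and the
#' sequence-vs-baseline modulation ratios, plus the PETH classification.
#'
#' @param unit a \linkS4class{UnitRecording}.
#' @param seqTable sequence table of the matching session.
#' @param session session index.
#' @param alpha significance level for the paired test.
#' @param peth logical; also build and classify the PETH (slower).
#' @return One-row data.frame (unit_id, region, session, n_trials,
#'   fr_sequence, fr_baseline, ff_sequence, ff_baseline, ff_modulation,
#'   fr_modulation, modulation_label, sequence_related), or NULL when the
#'   unit has no spikes or fewer than 2 usable trials in that session.
#' @export
unitSessionStats <- function(unit, seqTable, session, alpha = 0.05,
                             peth = TRUE) {
  st <- spikeTimes(unit)[[as.character(session)]]
  if (is.null(st)) return(NULL)
  w <- trialWindows(seqTable)
  if (nrow(w) < 2L) return(NULL)
  seqRates <- mapply(function(a, b) windowRate(st, c(a, b)),
                     w$seq_start, w$seq_end)
  baseRates <- mapply(function(a, b) windowRate(st, c(a, b)),
                      w$base_start, w$base_end)
  ffSeq <- unitFanoAcrossTrials(seqRates)
  ffBase <- unitFanoAcrossTrials(baseRates)
  label <- NA_character_; seqRel <- NA
  if (peth) {
    prof <- buildPETH(rep(list(st), nrow(w)), w$seq_start)
    prof <- classifyTaskRelated(prof, seqRates, baseRates, alpha)
    label <- modulation(prof)
    seqRel <- prof@sequenceRelated
  }
  data.frame(
    unit_id = unitId(unit), region = region(unit), session = session,
    n_trials = nrow(w),
    fr_sequence = mean(seqRates), fr_baseline = mean(baseRates),
    ff_sequence = ffSeq, ff_baseline = ffBase,
    ff_modulation = modulationRatio(ffSeq, ffBase),
    fr_modulation = modulationRatio(mean(seqRates), mean(baseRates)),
    modulation_label = label, sequence_related = seqRel)
}

#' Firing statistics table for many units across sessions
#'
#' @param units list of \linkS4class{UnitRecording}.
#' @param seqTables list of sequence tables indexed by session.
#' @param peth logical; include PETH classification per unit-session.
#' @param alpha significance level for the paired test.
#' @return data.frame, one row per unit-session with enough trials.
#' @export
spikeVariabilityTable <- function(units, seqTables, peth = FALSE,
                                  alpha = 0.05) {
  rows <- list()
  for (u in units) {
    for (s in as.integer(names(spikeTimes(u)))) {
      if (s > length(seqTables) || is.null(seqTables[[s]])) next
      r <- unitSessionStats(u, seqTables[[s]], s, alpha, peth = peth)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}

#' Flank-window Fano factors around first and last press
#'
#' Fano factors across trials for 1-s windows centered on the first and
#' last press of each sequence.
#'
#' @param unit a \linkS4class{UnitRecording}.
#' @param seqTable sequence table of the matching session.
#' @param session session index.
#' @return List with \code{ffFirst} and \code{ffLast}, or NULL when fewer
#'   than 2 usable trials.
#' @export
flankFano <- function(unit, seqTable, session) {
  st <- spikeTimes(unit)[[as.character(session)]]
  if (is.null(st)) return(NULL)
  w <- trialWindows(seqTable)
  if (nrow(w) < 2L) return(NULL)
  rFirst <- mapply(function(a, b) windowRate(st, c(a, b)),
                   w$first_flank_start, w$first_flank_end)
  rLast <- mapply(function(a, b) windowRate(st, c(a, b)),
                  w$last_flank_start, w$last_flank_end)
  list(ffFirst = unitFanoAcrossTrials(rFirst),
       ffLast = unitFanoAcrossTrials(rLast))
}
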