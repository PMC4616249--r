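## Coupling between behavioral and neural variability: Pearson correlation
## of sliding-window Fano traces, session-wise, with the smallest-session
## significance rule and Fisher-z averaging within animal.

#' Align two Fano traces into paired samples
#'
#' Windows are matched by their center trial index within each session;
#' unmatched windows are dropped.
#'
#' @param behaviorTrace,neuralTrace \linkS4class{FanoTrace} objects built
#'   over the same ordered trial axis with the same window size.
#' @return data.frame with session, center, x (behavior FF), y (neural FF).
#' @export
alignTraces <- function(behaviorTrace, neuralTrace) {
  if (windowSize(behaviorTrace) != windowSize(neuralTrace))
    stop("traces have different window sizes")
  bk <- paste(sessionIndices(behaviorTrace), centerIndices(behaviorTrace))
  nk <- paste(sessionIndices(neuralTrace), centerIndices(neuralTrace))
  i <- match(bk, nk)
  keep <- !is.na(i)
  data.frame(session = sessionIndices(behaviorTrace)[keep],
             center = centerIndices(behaviorTrace)[keep],
             x = fanoValues(behaviorTrace)[keep],
             y = fanoValues(neuralTrace)[i[keep]])
}

#' Critical Pearson r for a two-sided test
#'
#' The |r| threshold at which a two-sided t-test of zero correlation with
#' \code{n} pairs rejects at level \code{alpha}. Following the
#' smallest-session rule, every session of an animal is judged against the
#' threshold of its smallest session, guarding against sample-size bias.
#'
#' @param n number of pairs (>= 3).
#' @param alpha significance level.
#' @return Critical |r|.
#' @examples
#' criticalR(20)  # ~0.444
#' @export
criticalR <- function(n, alpha = 0.05) {
  if (n < 3L) stop("critical r requires n >= 3")
  tc <- stats::qt(1 - alpha / 2, df = n - 2L)
  tc / sqrt(n - 2L + tc^2)
}

#' Fisher-z average of correlation coefficients
#'
#' Transforms each r with arctanh, averages (unweighted by default; supply
#' \code{ns} for n - 3 weighting), and back-transforms with tanh. Values at
#' |r| = 1 are clipped with a warning.
#'
#' @param rs correlation coefficients.
#' @param ns optional sample sizes for weighted pooling.
#' @return Pooled r.
#' @examples
#' fisherZAverage(c(0, 0.8))  # ~0.5
#' @export
fisherZAverage <- function(rs, ns = NULL) {
  rs <- rs[!is.na(rs)]
  if (!length(rs)) return(NA_real_)
  if (any(abs(rs) >= 1)) {
    warning("clipping |r| = 1 before Fisher transform", call. = FALSE)
    rs <- pmin(pmax(rs, -1 + 1e-12), 1 - 1e-12)
  }
  z <- atanh(rs)
  zm <- if (is.null(ns)) mean(z) else
    stats::weighted.mean(z, pmax(ns - 3, 1))
  tanh(zm)
}

#' Session-wise correlation of two aligned traces
#'
#' @param pairs data.frame from \code{\link{alignTraces}}.
#' @param alpha significance level.
#' @return data.frame per session: session, n, r, critical_r, significant;
#'   the critical r of the smallest session is applied to all sessions.
#'   Attribute \code{pooled_r} holds the Fisher-z average across sessions,
#'   attribute \code{overall_r} the correlation of the concatenated trace.
#' @export
traceCorrelations <- function(pairs, alpha = 0.05) {
  pairs <- pairs[stats::complete.cases(pairs[, c("x", "y")]), , drop = FALSE]
  sess <- sort(unique(pairs$session))
  rows <- lapply(sess, function(s) {
    sub <- pairs[pairs$session == s, , drop = FALSE]
    r <- if (nrow(sub) >= 3L && stats::sd(sub$x) > 0 && stats::sd(sub$y) > 0)
      stats::cor(sub$x, sub$y) else NA_real_
    data.frame(session = s, n = nrow(sub), r = r)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab))
    return(structure(data.frame(session = integer(), n = integer(),
                                r = numeric(), critical_r = numeric(),
                                significant = logical()),
                     pooled_r = NA_real_, overall_r = NA_real_))
  usable <- tab$n[!is.na(tab$r)]
  rc <- if (length(usable) && min(usable) >= 3L) criticalR(min(usable), alpha)
        else NA_real_
  tab$critical_r <- rc
  tab$significant <- !is.na(tab$r) & !is.na(rc) & abs(tab$r) > rc
  attr(tab, "pooled_r") <- fisherZAverage(tab$r)
  attr(tab, "overall_r") <- if (nrow(pairs) >= 3L &&
                                stats::sd(pairs$x) > 0 &&
                                stats::sd(pairs$y) > 0)
    stats::cor(pairs$x, pairs$y) else NA_real_
  tab
}

.regionTrace <- function(units, kept, region, windowSize = 5L,
                         what = c("ff", "fr")) {
  # kept: sequence table across sessions, rows = the shared trial axis
  what <- match.arg(what)
  regUnits <- Filter(function(u) region(u) == region, units)
  if (!length(regUnits) || is.null(kept) || nrow(kept) < windowSize)
    return(NULL)
  perUnit <- list()
  for (u in regUnits) {
    rates <- rep(NA_real_, nrow(kept))
    for (s in unique(kept$session)) {
      st <- spikeTimes(u)[[as.character(s)]]
      if (is.null(st)) next
      idx <- which(kept$session == s)
      a <- kept$start_s[idx]
      b <- kept$start_s[idx] + kept$duration_s[idx]
      rates[idx] <- mapply(function(x, y) windowRate(st, c(x, y)), a, b)
    }
    tr <- if (what == "ff") slidingFano(rates, kept$session, windowSize)
          else .slidingMean(rates, kept$session, windowSize)
    perUnit[[length(perUnit) + 1L]] <- tr
  }
  # identical window grid for every unit (shared trial axis): average values
  vals <- rowMeans(do.call(cbind, lapply(perUnit, fanoValues)),
                   na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  tmpl <- perUnit[[1L]]
  new("FanoTrace", windowSize = as.integer(windowSize),
      values = as.numeric(vals), centerIndices = centerIndices(tmpl),
      sessionIndices = sessionIndices(tmpl))
}

.slidingMean <- function(values, sessions, windowSize) {
  half <- windowSize %/% 2L
  ms <- numeric(); ctr <- integer(); ses <- integer()
  for (s in sort(unique(sessions))) {
    idx <- which(sessions == s)
    if (length(idx) < windowSize) next
    for (start in 1:(length(idx) - windowSize + 1L)) {
      w <- idx[start:(start + windowSize - 1L)]
      ms <- c(ms, mean(values[w]))
      ctr <- c(ctr, w[half + 1L])
      ses <- c(ses, s)
    }
  }
  new("FanoTrace", windowSize = as.integer(windowSize), values = ms,
      centerIndices = ctr, sessionIndices = ses)
}

#' Behavior-neural variability coupling report
#'
#' For one animal: sliding-window Fano traces of sequence frequency and
#' duration are correlated, session by session, with the across-unit mean
#' neural Fano trace of each region (trials = sequences, rates from the
#' sequence window), with the M1 x DS trace pair, and with the mean firing
#' rate trace (all units) as a specificity control.
#'
#' @param seqTable sequence table across sessions for the animal.
#' @param units list of \linkS4class{UnitRecording} recorded in that
#'   animal.
#' @param windowSize sliding window in trials (default 5).
#' @param alpha significance level.
#' @return Named list of per-pair correlation tables (see
#'   \code{\link{traceCorrelations}}); pairs without data are omitted.
#' @export
couplingReport <- function(seqTable, units, windowSize = 5L, alpha = 0.05) {
  sessions <- sort(unique(seqTable$session))
  seqTables <- vector("list", max(sessions))
  ord <- order(seqTable$session, seqTable$start_s)
  seqTable <- seqTable[ord, , drop = FALSE]
  for (s in sessions)
    seqTables[[s]] <- seqTable[seqTable$session == s, , drop = FALSE]
  # behavior traces over trials that survive the baseline-window drop, so
  # neural and behavioral windows share a trial axis
  keptTables <- lapply(seqTables, function(t) {
    if (is.null(t)) return(NULL)
    t[t$start_s - 5 >= 0, , drop = FALSE]
  })
  kept <- do.call(rbind, keptTables)
  freqTrace <- slidingFano(kept$frequency_hz, kept$session, windowSize)
  durTrace <- slidingFano(kept$duration_s, kept$session, windowSize)
  m1 <- .regionTrace(units, kept, "M1", windowSize, "ff")
  ds <- .regionTrace(units, kept, "DS", windowSize, "ff")
  frAll <- .meanRateTrace(units, kept, windowSize)
  out <- list()
  addPair <- function(name, a, b) {
    if (is.null(a) || is.null(b)) return()
    out[[name]] <<- traceCorrelations(alignTraces(a, b), alpha)
  }
  addPair("M1_ff_x_frequency_ff", freqTrace, m1)
  addPair("M1_ff_x_duration_ff", durTrace, m1)
  addPair("DS_ff_x_frequency_ff", freqTrace, ds)
  addPair("DS_ff_x_duration_ff", durTrace, ds)
  if (!is.null(m1) && !is.null(ds))
    out[["M1_ff_x_DS_ff"]] <- traceCorrelations(alignTraces(m1, ds), alpha)
  addPair("fr_x_frequency_ff", freqTrace, frAll)
  addPair("fr_x_duration_ff", durTrace, frAll)
  out
}

.meanRateTrace <- function(units, kept, windowSize) {
  both <- lapply(.REGIONS, function(rg)
    .regionTrace(units, kept, rg, windowSize, "fr"))
  both <- Filter(Negate(is.null), both)
  if (!length(both)) return(NULL)
  if (length(both) == 1L) return(both[[1L]])
  k1 <- paste(sessionIndices(both[[1L]]), centerIndices(both[[1L]]))
  k2 <- paste(sessionIndices(both[[2L]]), centerIndices(both[[2L]]))
  i <- match(k1, k2)
  keep <- !is.na(i)
  new("FanoTrace", windowSize = windowSize(both[[1L]]),
      values = (fanoValues(both[[1L]])[keep] +
                fanoValues(both[[2L]])[i[keep]]) / 2,
      centerIndices = centerIndices(both[[1L]])[keep],
      sessionIndices = sessionIndices(both[[1L]])[keep])
}
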