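## Variance / Fano-factor statistics of sequence features, per session and
## as sliding-window traces over the ordered trial axis.

#' Fano factor of a sample
#'
#' Sample variance (n - 1 denominator) divided by the sample mean. Used for
#' trial-to-trial variability of behavioral features and firing rates.
#'
#' @param values numeric vector, n >= 2, mean > 0.
#' @return The Fano factor (>= 0).
#' @examples
#' fanoFactor(c(1, 2, 3))  # var 1 / mean 2 = 0.5
#' @export
fanoFactor <- function(values) {
  if (length(values) < 2L)
    stop("Fano factor requires at least 2 values")
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    stop("Fano factor requires a positive mean")
  stats::var(values) / m
}

.fanoOrNA <- function(values) {
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  stats::var(values) / m
}

#' Extract an ordered feature series from a sequence table
#'
#' Trials are sequences ordered by start time within a session and by
#' session index across sessions.
#'
#' @param seqTable sequence table (rows from \code{\link{sessionSequences}},
#'   possibly concatenated across sessions) for one animal.
#' @param feature \code{"frequency"}, \code{"duration"} or \code{"length"}.
#' @return List with \code{values} and \code{sessions} (parallel vectors).
#' @export
featureSeries <- function(seqTable,
                          feature = c("frequency", "duration", "length")) {
  feature <- match.arg(feature)
  col <- switch(feature, frequency = "frequency_hz",
                duration = "duration_s", length = "length")
  ord <- order(seqTable$session, seqTable$start_s)
  list(values = as.numeric(seqTable[[col]][ord]),
       sessions = as.integer(seqTable$session[ord]))
}

#' Per-session mean, variance and Fano factor
#'
#' @param values feature values in trial order.
#' @param sessions parallel session index per trial.
#' @return data.frame with one row per session: session, n, mean, variance,
#'   fano; sessions with fewer than 2 trials yield \code{NA} statistics.
#' @export
sessionVariability <- function(values, sessions) {
  stopifnot(length(values) == length(sessions))
  out <- lapply(sort(unique(sessions)), function(s) {
    v <- values[sessions == s]
    data.frame(session = s, n = length(v), mean = mean(v),
               variance = if (length(v) >= 2L) stats::var(v) else NA_real_,
               fano = .fanoOrNA(v))
  })
  do.call(rbind, out)
}

#' Sliding-window Fano-factor trace
#'
#' Fano factors in a moving window of \code{windowSize} consecutive trials
#' shifted by one trial. Windows never span session boundaries; a session
#' shorter than the window contributes no windows. The window center index
#' refers to the global trial order.
#'
#' @param values feature values in trial order.
#' @param sessions parallel session index per trial.
#' @param windowSize odd window length in trials: 3, 5 or 7.
#' @return A \linkS4class{FanoTrace}.
#' @export
slidingFano <- function(values, sessions, windowSize = 5L) {
  windowSize <- as.integer(windowSize)
  if (windowSize < 3L || windowSize %% 2L == 0L)
    stop("windowSize must be an odd integer >= 3")
  stopifnot(length(values) == length(sessions))
  half <- windowSize %/% 2L
  ffs <- numeric(); ctr <- integer(); ses <- integer()
  for (s in sort(unique(sessions))) {
    idx <- which(sessions == s)
    if (length(idx) < windowSize) next
    for (start in 1:(length(idx) - windowSize + 1L)) {
      w <- idx[start:(start + windowSize - 1L)]
      ffs <- c(ffs, .fanoOrNA(values[w]))
      ctr <- c(ctr, w[half + 1L])
      ses <- c(ses, s)
    }
  }
  ffs[is.na(ffs)] <- NA_real_
  new("FanoTrace", windowSize = windowSize,
      values = as.numeric(ffs), centerIndices = ctr, sessionIndices = ses)
}

#' Matched-sequence filter
#'
#' Restricts to sequences with a duration of 0.2-2 s (inclusive) and a
#' frequency strictly above 2 Hz, matching execution speed across sessions
#' so variability comparisons are not confounded by gross kinematic change.
#'
#' @param seqTable sequence table.
#' @return The filtered table (attributes subset accordingly).
#' @export
matchedSequenceFilter <- function(seqTable) {
  keep <- seqTable$duration_s >= 0.2 & seqTable$duration_s <= 2.0 &
    seqTable$frequency_hz > 2.0
  out <- seqTable[keep, , drop = FALSE]
  for (a in c("pressTimes", "hitIndices")) {
    if (!is.null(attr(seqTable, a)))
      attr(out, a) <- attr(seqTable, a)[keep]
  }
  out
}

#' Variability split by reinforcement outcome
#'
#' Per session and feature, variance and Fano factor computed independently
#' for reinforced and non-reinforced sequences.
#'
#' @param seqTable sequence table with a \code{reinforced} column.
#' @return data.frame with columns session, group (RF/nonRF), feature,
#'   n, mean, variance, fano; groups with fewer than 2 members yield
#'   \code{NA}.
#' @export
reinforcedSplitVariability <- function(seqTable) {
  out <- list()
  for (s in sort(unique(seqTable$session))) {
    sub <- seqTable[seqTable$session == s, , drop = FALSE]
    for (grp in c("RF", "nonRF")) {
      g <- sub[sub$reinforced == (grp == "RF"), , drop = FALSE]
      for (feat in c("frequency", "duration")) {
        v <- g[[if (feat == "frequency") "frequency_hz" else "duration_s"]]
        out[[length(out) + 1L]] <- data.frame(
          session = s, group = grp, feature = feat, n = length(v),
          mean = if (length(v)) mean(v) else NA_real_,
          variance = if (length(v) >= 2L) stats::var(v) else NA_real_,
          fano = .fanoOrNA(v))
      }
    }
  }
  do.call(rbind, out)
}
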