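## Percentile bootstrap for a difference of group means, used to validate
## post hoc group comparisons without normality assumptions.

#' Bootstrap inference for a difference of means
#'
#' Resamples each group independently with replacement at its own size and
#' computes the difference of means per resample; the percentile interval
#' of those draws is the confidence interval. The two-sided p-value imposes
#' the null by resampling both groups from the pooled data
#' (\code{nullMethod = "pooled"}, the standard bootstrap hypothesis test);
#' \code{"recentered"} instead shifts the independent-group draws to zero
#' mean, which is slightly anti-conservative at small n.
#'
#' @param groupA,groupB numeric vectors (n >= 2 each).
#' @param nResamples number of bootstrap resamples (default 100000).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param ciType \code{"two.sided"} (2.5/97.5 percentiles, default) or
#'   \code{"one.sided"} (5/95 percentiles).
#' @param nullMethod \code{"pooled"} or \code{"recentered"}; see above.
#' @return List of class \code{"bootstrapResult"}: observedDiff, ciLow,
#'   ciHigh, nullExceedanceP, resampleCount, seed, and the resampled
#'   differences in \code{draws}.
#' @examples
#' bootstrapDiffMeans(c(1, 2, 3), c(11, 12, 13), nResamples = 1000, seed = 1)
#' @export
bootstrapDiffMeans <- function(groupA, groupB, nResamples = 100000L,
                               seed = NULL,
                               ciType = c("two.sided", "one.sided"),
                               nullMethod = c("pooled", "recentered")) {
  ciType <- match.arg(ciType)
  nullMethod <- match.arg(nullMethod)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 observations")
  if (!is.null(seed)) set.seed(as.integer(seed))
  nA <- length(groupA); nB <- length(groupB)
  obs <- mean(groupA) - mean(groupB)
  mA <- matrix(sample(groupA, nA * nResamples, replace = TRUE), nResamples)
  mB <- matrix(sample(groupB, nB * nResamples, replace = TRUE), nResamples)
  draws <- rowMeans(mA) - rowMeans(mB)
  probs <- if (ciType == "two.sided") c(0.025, 0.975) else c(0.05, 0.95)
  ci <- stats::quantile(draws, probs, names = FALSE)
  if (nullMethod == "pooled") {
    pool <- c(groupA, groupB)
    nA0 <- matrix(sample(pool, nA * nResamples, replace = TRUE), nResamples)
    nB0 <- matrix(sample(pool, nB * nResamples, replace = TRUE), nResamples)
    nullDraws <- rowMeans(nA0) - rowMeans(nB0)
  } else {
    nullDraws <- draws - obs
  }
  p <- mean(abs(nullDraws) >= abs(obs))
  structure(list(observedDiff = obs, ciLow = ci[1L], ciHigh = ci[2L],
                 nullExceedanceP = p, resampleCount = nResamples,
                 seed = seed, draws = draws),
            class = "bootstrapResult")
}

#' @export
print.bootstrapResult <- function(x, ...) {
  cat(sprintf("Bootstrap difference of means (%d resamples%s)\n",
              x$resampleCount,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  cat(sprintf("  observed diff %.4g, CI [%.4g, %.4g], p = %.4g\n",
              x$observedDiff, x$ciLow, x$ciHigh, x$nullExceedanceP))
  invisible(x)
}

#' Histogram table of bootstrap draws
#'
#' @param result a \code{bootstrapResult}.
#' @param breaks number of histogram cells.
#' @return data.frame with mid, count.
#' @export
bootstrapHistogram <- function(result, breaks = 50L) {
  h <- graphics::hist(result$draws, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}
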