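## Cross-session unit stability: waveform snippets from all sessions are
## pooled to compute common principal axes; each session's cloud is then
## projected into that space and consecutive-session centroid displacement
## is compared to the previous session's cluster dispersion.

#' Pooled principal axes over all sessions' waveforms
#'
#' Stacks every session's snippet matrix and computes the first two
#' principal components with a deterministic sign convention (the largest
#' absolute loading of each axis is positive).
#'
#' @param waveformList list of snippet matrices (rows = spikes, columns =
#'   voltage samples), all with the same column count.
#' @param nAxes number of axes to keep (default 2).
#' @return List with \code{axes} (samples x nAxes matrix of unit-norm,
#'   orthogonal loadings ordered by explained variance), \code{center}
#'   (pooled mean vector), \code{varExplained} (proportions).
#' @export
pooledPrincipalAxes <- function(waveformList, nAxes = 2L) {
  X <- do.call(rbind, waveformList)
  if (is.null(X) || nrow(X) < 2L || ncol(X) < 2L)
    stop("need at least 2 snippets with at least 2 samples each")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  pos <- pc$sdev > max(pc$sdev) * 1e-8
  if (sum(pos) < nAxes)
    stop("waveform cloud is rank-deficient: fewer than ",
         nAxes, " nonzero-variance directions")
  axes <- pc$rotation[, seq_len(nAxes), drop = FALSE]
  for (j in seq_len(ncol(axes))) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  list(axes = axes, center = pc$center,
       varExplained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nAxes)])
}

#' Session cluster centroid and dispersion in pooled PC space
#'
#' @param sessionWaveforms snippet matrix of one session (>= 2 rows).
#' @param axes,center from \code{\link{pooledPrincipalAxes}}.
#' @return List with \code{centroid} and \code{sd}, each one value per
#'   component.
#' @export
sessionClusterStats <- function(sessionWaveforms, axes, center) {
  if (nrow(sessionWaveforms) < 2L)
    stop("need at least 2 snippets in the session")
  proj <- sweep(sessionWaveforms, 2L, center) %*% axes
  list(centroid = colMeans(proj), sd = apply(proj, 2L, stats::sd))
}

#' Assess cross-session stability of one unit
#'
#' A unit is stable when, for every consecutive session pair and in each of
#' the first two pooled principal components, the later session's centroid
#' lies within the earlier centroid plus/minus \code{k} times the earlier
#' session's cluster SD (inclusive bound; default k = 1.96).
#'
#' @param unit a \linkS4class{UnitRecording} with waveform matrices for at
#'   least 2 sessions, each with at least 2 snippets.
#' @param k dispersion multiplier (default 1.96).
#' @return List with \code{table} (data.frame: pair, pc, displacement,
#'   bound, pass), \code{overallStable} (logical), and
#'   \code{contiguous} (FALSE when intermediate sessions are missing, in
#'   which case only consecutive recorded pairs are evaluated).
#' @export
assessStability <- function(unit, k = 1.96) {
  wf <- waveforms(unit)
  sess <- sort(as.integer(names(wf)))
  if (length(sess) < 2L)
    stop("stability assessment needs waveforms from at least 2 sessions")
  contiguous <- all(diff(sess) == 1L)
  if (!contiguous)
    warning(sprintf("unit %s: sessions not contiguous (%s); evaluating %s",
                    unitId(unit), paste(sess, collapse = ","),
                    "consecutive recorded pairs only"), call. = FALSE)
  pca <- pooledPrincipalAxes(wf)
  stats <- lapply(as.character(sess), function(s)
    sessionClusterStats(wf[[s]], pca$axes, pca$center))
  rows <- list()
  for (i in seq_len(length(sess) - 1L)) {
    d <- abs(stats[[i + 1L]]$centroid - stats[[i]]$centroid)
    bound <- k * stats[[i]]$sd
    for (pc in 1:2)
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = unitId(unit),
        pair = sprintf("%d-%d", sess[i], sess[i + 1L]), pc = pc,
        displacement = d[pc], bound = bound[pc],
        # inclusive bound, robust to float rounding at exact equality
        pass = d[pc] <= bound[pc] * (1 + 1e-9) + 1e-12)
  }
  tab <- do.call(rbind, rows)
  list(table = tab, overallStable = all(tab$pass), contiguous = contiguous)
}

#' Stability table for a set of units
#'
#' @param units list of \linkS4class{UnitRecording}.
#' @param k dispersion multiplier.
#' @return data.frame: unit_id, region, n_sessions, overall_stable.
#' @export
stabilityTable <- function(units, k = 1.96) {
  rows <- lapply(units, function(u) {
    res <- tryCatch(assessStability(u, k), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(unit_id = unitId(u), region = region(u),
               n_sessions = length(waveforms(u)),
               overall_stable = res$overallStable)
  })
  do.call(rbind, rows)
}
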