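## End-to-end orchestration: simulate (optional) -> segment -> behavioral
## variability -> spike variability -> stability -> coupling -> bootstrap,
## writing one CSV per stage plus a session-trend summary.

#' Pipeline configuration
#'
#' Collects every analysis constant in one place so each is overridable:
#' gap threshold 2 s, end-target bound 0.660 s, Fano window 5 trials,
#' baseline window [-5, -2) s, PETH bins 20 ms stepped 1 ms with the
#' 20-consecutive-bin rule, stability k 1.96, bootstrap 100000 resamples,
#' alpha 0.05.
#'
#' @param inputDir dataset directory (with manifest.yaml); NULL to
#'   simulate.
#' @param outputDir output directory for stage CSVs.
#' @param simulateProfile fixture profile when simulating.
#' @param gapThreshold,endTargetBound,ffWindow,baselineWindow,peth,
#'   stabilityK,bootstrapReps,alpha analysis constants.
#' @param seed master seed.
#' @return List of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(inputDir = NULL, outputDir,
                           simulateProfile = "tiny", gapThreshold = 2.0,
                           endTargetBound = 0.660, ffWindow = 5L,
                           baselineWindow = c(-5, -2), peth = FALSE,
                           stabilityK = 1.96, bootstrapReps = 100000L,
                           alpha = 0.05, seed = 1L) {
  structure(list(inputDir = inputDir, outputDir = outputDir,
                 simulateProfile = simulateProfile,
                 gapThreshold = gapThreshold,
                 endTargetBound = endTargetBound,
                 ffWindow = as.integer(ffWindow),
                 baselineWindow = baselineWindow, peth = peth,
                 stabilityK = stabilityK,
                 bootstrapReps = as.integer(bootstrapReps), alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

.writeStage <- function(tab, outputDir, name) {
  if (is.null(tab) || !nrow(tab)) return(invisible(NULL))
  path <- file.path(outputDir, paste0(name, ".csv"))
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(x) round(x, 8))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return Invisibly, a list with all stage tables: sessionSummaries,
#'   sequences, behaviorVariability, fanoTraces, spikeVariability,
#'   stability, coupling, bootstrap, trendSummary.
#' @export
runPipeline <- function(config) {
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  dataDir <- config$inputDir
  if (is.null(dataDir)) {
    dataDir <- file.path(config$outputDir, "dataset")
    stage("simulate",
          makeFixture(config$simulateProfile, dataDir,
                      seed = config$seed, force = TRUE))
  }
  ds <- stage("read", readDataset(dataDir))

  summaries <- list(); seqTabs <- list()
  stage("segment", for (a in names(ds$events)) {
    for (ev in ds$events[[a]]) {
      seqTabs[[length(seqTabs) + 1L]] <-
        sessionSequences(ev, config$gapThreshold)
      summaries[[length(summaries) + 1L]] <-
        sessionSummary(ev, config$endTargetBound, config$gapThreshold)
    }
  })
  seqAll <- do.call(rbind, seqTabs)
  sumAll <- do.call(rbind, summaries)

  behVar <- list(); traces <- list()
  stage("behavior-var", for (a in names(ds$events)) {
    sub <- seqAll[seqAll$animal == a, , drop = FALSE]
    if (!nrow(sub)) next
    for (feat in c("frequency", "duration")) {
      fs <- featureSeries(sub, feat)
      sv <- sessionVariability(fs$values, fs$sessions)
      sv$animal <- a; sv$feature <- feat
      behVar[[length(behVar) + 1L]] <- sv
      tr <- slidingFano(fs$values, fs$sessions, config$ffWindow)
      if (length(fanoValues(tr)))
        traces[[length(traces) + 1L]] <- data.frame(
          animal = a, feature = feat,
          session = sessionIndices(tr), center = centerIndices(tr),
          ff = fanoValues(tr))
    }
  })
  behVar <- do.call(rbind, behVar)
  traces <- do.call(rbind, traces)

  spikeVar <- NULL; stab <- NULL; coup <- list()
  if (length(ds$units)) {
    sv <- list(); stabs <- list()
    stage("spike-var", for (a in names(ds$units)) {
      sub <- seqAll[seqAll$animal == a, , drop = FALSE]
      byS <- vector("list", max(sub$session))
      for (s in unique(sub$session))
        byS[[s]] <- sub[sub$session == s, , drop = FALSE]
      tab <- spikeVariabilityTable(ds$units[[a]], byS,
                                   peth = config$peth,
                                   alpha = config$alpha)
      if (!is.null(tab)) { tab$animal <- a; sv[[a]] <- tab }
    })
    spikeVar <- do.call(rbind, sv)
    stage("stability", for (a in names(ds$units)) {
      tab <- stabilityTable(ds$units[[a]], config$stabilityK)
      if (!is.null(tab)) { tab$animal <- a; stabs[[a]] <- tab }
    })
    stab <- do.call(rbind, stabs)
    stage("couple", for (a in names(ds$units)) {
      sub <- seqAll[seqAll$animal == a, , drop = FALSE]
      cr <- couplingReport(sub, ds$units[[a]], config$ffWindow,
                           config$alpha)
      for (p in names(cr)) {
        tab <- cr[[p]]
        if (!nrow(tab)) next
        tab$animal <- a; tab$pair <- p
        tab$pooled_r <- attr(cr[[p]], "pooled_r")
        tab$overall_r <- attr(cr[[p]], "overall_r")
        coup[[length(coup) + 1L]] <- tab
      }
    })
  }
  coup <- if (length(coup)) do.call(rbind, coup) else NULL

  boot <- NULL
  if (!is.null(behVar)) {
    firstS <- min(behVar$session); lastS <- max(behVar$session)
    a1 <- behVar$fano[behVar$feature == "frequency" &
                      behVar$session == firstS]
    a2 <- behVar$fano[behVar$feature == "frequency" &
                      behVar$session == lastS]
    a1 <- a1[!is.na(a1)]; a2 <- a2[!is.na(a2)]
    if (length(a1) >= 2L && length(a2) >= 2L && firstS != lastS) {
      b <- stage("bootstrap",
                 bootstrapDiffMeans(a1, a2, config$bootstrapReps,
                                    seed = config$seed))
      boot <- data.frame(comparison = "frequency_ff_first_vs_last",
                         observed_diff = b$observedDiff,
                         ci_low = b$ciLow, ci_high = b$ciHigh,
                         p = b$nullExceedanceP, reps = b$resampleCount)
    }
  }

  trend <- NULL
  if (!is.null(behVar)) {
    trend <- do.call(rbind, lapply(split(behVar, behVar$feature),
      function(d) {
        m <- stats::aggregate(fano ~ session, d, mean)
        rho <- if (nrow(m) >= 3L)
          stats::cor(m$session, m$fano, method = "spearman") else NA_real_
        data.frame(feature = d$feature[1L], spearman_rho = rho,
                   decreasing = !is.na(rho) && rho < 0)
      }))
  }

  out <- list(sessionSummaries = sumAll, sequences = seqAll,
              behaviorVariability = behVar, fanoTraces = traces,
              spikeVariability = spikeVar, stability = stab,
              coupling = coup, bootstrap = boot, trendSummary = trend)
  .writeStage(sumAll, config$outputDir, "session_summaries")
  .writeStage(seqAll, config$outputDir, "sequences")
  .writeStage(behVar, config$outputDir, "behavior_variability")
  .writeStage(traces, config$outputDir, "fano_traces")
  .writeStage(spikeVar, config$outputDir, "spike_variability")
  .writeStage(stab, config$outputDir, "stability")
  .writeStage(coup, config$outputDir, "coupling")
  .writeStage(boot, config$outputDir, "bootstrap")
  .writeStage(trend, config$outputDir, "trend_summary")
  invisible(out)
}
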