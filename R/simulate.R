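## Synthetic behavior and spike generator with known ground truth.
## Behavior: sequences of lognormal IPIs (truncated below the 2-s gap
## threshold so generative bouts are exactly recoverable by segmentation),
## separated by pauses > 2 s, with an escalating covert frequency target.
## Frequency variability is controlled by the IPI log-SD (falling across
## sessions) and duration variability by the length distribution (rising),
## mirroring the programmed dissociation of the two features.
## Spikes: per-trial gain-modulated Poisson processes whose gain dispersion
## falls across sessions at constant mean rate, optionally coupled to the
## behavioral frequency deviation.

.substream <- function(seed, k) {
  (as.integer(seed) %% 100000L) * 10007L + 97L * k
}

#' Parameters of the behavioral generator
#'
#' Defaults emulate the 9-session training schedule: covert targets
#' 0 (free), 0.375, 0.75, 0.75, 1.5, 3, 3, 4.5, 4.5 Hz; IPI medians
#' falling toward 0.22 s with falling log-SD (programmed decrease of
#' frequency variability); sequence-length mean rising (programmed
#' increase of duration variability); pauses bounded below by 2.05 s so
#' segmentation at the 2-s threshold recovers the generated bouts exactly.
#'
#' @param nSessions number of sessions.
#' @param targetFrequencies covert target per session, Hz (0 = free).
#' @param sequencesPerMin target sequence rate per session (sets pause
#'   lengths).
#' @param lengthMean per-session mean of the length model
#'   (length = 2 + NegBinomial(mu = lengthMean, size = lengthDispersion)).
#' @param lengthDispersion per-session negative-binomial size; large values
#'   approach a shifted Poisson, small values inflate length variance (the
#'   duration-variability knob, falling across sessions).
#' @param ipiMedian per-session lognormal IPI median, seconds.
#' @param ipiLogSd per-session lognormal log-SD (frequency-variability
#'   knob).
#' @param pauseMin minimum inter-bout pause, seconds (> 2).
#' @param pCheck probability of a magazine head entry after a sequence.
#' @param sessionDuration seconds per session.
#' @return List of class \code{"behaviorGenParams"}.
#' @export
behaviorGenParams <- function(
    nSessions = 9L,
    targetFrequencies = c(0, 0.375, 0.75, 0.75, 1.5, 3, 3, 4.5, 4.5),
    sequencesPerMin = seq(1.8, 3.5, length.out = nSessions),
    lengthMean = seq(0.8, 7, length.out = nSessions),
    lengthDispersion = exp(seq(log(50), log(1.5),
                               length.out = nSessions)),
    ipiMedian = c(0.65, 0.58, 0.50, 0.44, 0.37, 0.31, 0.27, 0.24, 0.22),
    ipiLogSd = seq(0.45, 0.15, length.out = nSessions),
    pauseMin = 2.05, pCheck = 0.25, sessionDuration = 600) {
  stopifnot(length(targetFrequencies) == nSessions,
            length(ipiMedian) == nSessions,
            length(ipiLogSd) == nSessions, all(ipiLogSd > 0),
            all(ipiMedian > 0), pauseMin > 2)
  # warn when the IPI model would routinely exceed the 2-s gap threshold
  pOver <- stats::plnorm(2, log(ipiMedian), ipiLogSd, lower.tail = FALSE)
  if (any(pOver > 0.01))
    warning(sprintf(
      "session(s) %s: P(IPI >= 2 s) > 1%%; truncation will distort the IPI model",
      paste(which(pOver > 0.01), collapse = ",")), call. = FALSE)
  structure(list(nSessions = as.integer(nSessions),
                 targetFrequencies = targetFrequencies,
                 sequencesPerMin = sequencesPerMin, lengthMean = lengthMean,
                 lengthDispersion = rep_len(lengthDispersion, nSessions),
                 ipiMedian = ipiMedian, ipiLogSd = ipiLogSd,
                 pauseMin = pauseMin, pCheck = pCheck,
                 sessionDuration = sessionDuration),
            class = "behaviorGenParams")
}

.rIpi <- function(n, meanlog, sdlog, cap = 1.999) {
  # lognormal truncated below the gap threshold
  x <- stats::rlnorm(n, meanlog, sdlog)
  for (it in 1:20) {
    bad <- x >= cap
    if (!any(bad)) break
    x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
  }
  pmin(x, cap)
}

#' Generate synthetic session event logs
#'
#' Draws bouts of lognormal IPIs separated by pauses above the gap
#' threshold, inserts magazine checks, and runs the online reinforcement
#' rule (covert-target scan with window reset) to stamp reinforcer events
#' at the presses that complete a hit.
#'
#' @param params a \code{\link{behaviorGenParams}} list.
#' @param animalId animal label.
#' @param seed integer seed.
#' @return List with \code{events} (list of \linkS4class{SessionEvents}),
#'   \code{truth} (list: \code{sessions} data.frame of generative
#'   parameters, \code{sequences} data.frame of realized per-sequence
#'   features with bout identity).
#' @export
generateBehavior <- function(params, animalId = "A1", seed = 1L) {
  set.seed(.substream(seed, 1L))
  events <- vector("list", params$nSessions)
  seqRows <- list()
  for (s in seq_len(params$nSessions)) {
    target <- params$targetFrequencies[s]
    sch <- scheduleEntry("frequency_target", targetFrequency = target)
    dur <- params$sessionDuration
    pauseExtra <- max(60 / params$sequencesPerMin[s] - params$pauseMin - 2, 1)
    meanlog <- log(params$ipiMedian[s])
    press <- numeric(); he <- numeric(); rf <- numeric()
    t <- 0
    repeat {
      pause <- params$pauseMin + stats::rexp(1, 1 / pauseExtra)
      t0 <- t + pause
      L <- 2L + stats::rnbinom(1L, size = params$lengthDispersion[s],
                               mu = params$lengthMean[s])
      ipis <- .rIpi(L - 1L, meanlog, params$ipiLogSd[s])
      p <- t0 + c(0, cumsum(ipis))
      if (p[length(p)] >= dur - 0.5) break
      press <- c(press, p)
      hits <- detectCovertTargets(ipis, sch@summedIpiBound, resetOnHit = TRUE)
      if (length(hits)) rf <- c(rf, p[hits])
      feats <- sequenceFeatures(p)
      seqRows[[length(seqRows) + 1L]] <- data.frame(
        animal = animalId, session = s, start_s = p[1L],
        length = L, frequency_hz = feats$frequency,
        duration_s = feats$duration, reinforced = length(hits) > 0L)
      t <- p[length(p)]
      if (stats::runif(1) < params$pCheck) {
        heT <- t + stats::runif(1, 0.3, 1.5)
        he <- c(he, heT)
      }
    }
    events[[s]] <- sessionEvents(animalId, s, sch, press, sort(he),
                                 sort(rf), dur)
  }
  truthSessions <- data.frame(
    session = seq_len(params$nSessions),
    target_frequency = params$targetFrequencies,
    ipi_median = params$ipiMedian, ipi_log_sd = params$ipiLogSd,
    length_mean = params$lengthMean)
  list(events = events,
       truth = list(sessions = truthSessions,
                    sequences = do.call(rbind, seqRows)))
}

#' Parameters of the spike generator
#'
#' Each unit fires as a Poisson process at baseline rate \code{lambda}
#' outside sequences and at \code{lambda * gain} inside each sequence
#' window, with per-trial gain
#' \eqn{g = exp(\beta z + \epsilon - (\sigma_s^2 + \beta^2) / 2)},
#' \eqn{\epsilon \sim N(0, \sigma_s)}, where z is the session-standardized
#' frequency deviation of that sequence. The correction term keeps the
#' expected gain at 1, so mean rates stay flat while gain dispersion
#' (\code{gainLogSd}, falling across sessions) sets trial-to-trial rate
#' variability.
#'
#' @param nUnitsM1,nUnitsDS unit counts per region.
#' @param lambda baseline rate(s) in Hz; recycled across units.
#' @param gainLogSd per-session gain log-SD (neural-variability knob).
#' @param beta coupling of the trial gain to the behavioral frequency
#'   z-deviation (0 = uncoupled).
#' @param nSamples waveform snippet length in samples.
#' @param snippetNoiseSd waveform noise SD (template units).
#' @param driftPerSession optional per-session waveform drift magnitude
#'   (template units) for instability tests; 0 = stationary.
#' @param snippetCap maximum snippets stored per unit and session.
#' @param nSessions number of sessions (must match the behavior).
#' @return List of class \code{"neuralGenParams"}.
#' @export
neuralGenParams <- function(nUnitsM1 = 4L, nUnitsDS = 2L, lambda = 6,
                            gainLogSd = seq(0.9, 0.2,
                                            length.out = nSessions),
                            beta = 0, nSamples = 32L, snippetNoiseSd = 6,
                            driftPerSession = 0, snippetCap = 200L,
                            nSessions = 9L) {
  stopifnot(all(lambda > 0), all(gainLogSd >= 0),
            length(gainLogSd) == nSessions)
  structure(list(nUnitsM1 = as.integer(nUnitsM1),
                 nUnitsDS = as.integer(nUnitsDS), lambda = lambda,
                 gainLogSd = gainLogSd, beta = beta,
                 nSamples = as.integer(nSamples),
                 snippetNoiseSd = snippetNoiseSd,
                 driftPerSession = driftPerSession,
                 snippetCap = as.integer(snippetCap),
                 nSessions = as.integer(nSessions)),
            class = "neuralGenParams")
}

.waveformTemplate <- function(nSamples, amp) {
  x <- seq_len(nSamples)
  amp * (exp(-(x - nSamples * 0.3)^2 / (nSamples * 0.6)) -
         0.55 * exp(-(x - nSamples * 0.6)^2 / (nSamples * 1.8)))
}

.poissonTimes <- function(rate, a, b) {
  n <- stats::rpois(1L, rate * (b - a))
  if (!n) return(numeric())
  sort(stats::runif(n, a, b))
}

#' Generate synthetic spike recordings driven by behavior
#'
#' @param behavior result of \code{\link{generateBehavior}}.
#' @param params a \code{\link{neuralGenParams}} list.
#' @param seed integer seed.
#' @return List of \linkS4class{UnitRecording}.
#' @export
generateSpikes <- function(behavior, params, seed = 1L) {
  set.seed(.substream(seed, 2L))
  stopifnot(length(behavior$events) == params$nSessions)
  nUnits <- params$nUnitsM1 + params$nUnitsDS
  regions <- rep(c("M1", "DS"), c(params$nUnitsM1, params$nUnitsDS))
  lambda <- rep_len(params$lambda, nUnits)
  amp <- stats::runif(nUnits, 60, 120)
  seqTruth <- behavior$truth$sequences
  units <- vector("list", nUnits)
  for (u in seq_len(nUnits)) {
    tmpl <- .waveformTemplate(params$nSamples, amp[u])
    st <- list(); wf <- list()
    for (s in seq_len(params$nSessions)) {
      ev <- behavior$events[[s]]
      seqs <- seqTruth[seqTruth$session == s, , drop = FALSE]
      z <- if (nrow(seqs) >= 2L && stats::sd(seqs$frequency_hz) > 0)
        as.numeric(scale(seqs$frequency_hz)) else rep(0, nrow(seqs))
      sg <- params$gainLogSd[s]
      gains <- exp(params$beta * z +
                   stats::rnorm(nrow(seqs), 0, sg) -
                   (sg^2 + params$beta^2) / 2)
      # piecewise-constant rate: lambda outside, lambda * gain inside
      spikes <- numeric()
      prevEnd <- 0
      for (i in seq_len(nrow(seqs))) {
        a <- seqs$start_s[i]; b <- a + seqs$duration_s[i]
        spikes <- c(spikes, .poissonTimes(lambda[u], prevEnd, a))
        spikes <- c(spikes, .poissonTimes(lambda[u] * gains[i], a, b))
        prevEnd <- b
      }
      spikes <- c(spikes,
                  .poissonTimes(lambda[u], prevEnd, sessionDuration(ev)))
      spikes <- sort(unique(spikes))
      st[[as.character(s)]] <- spikes
      nSnip <- min(length(spikes), params$snippetCap)
      if (nSnip >= 2L) {
        drift <- params$driftPerSession * (s - 1L)
        wf[[as.character(s)]] <- matrix(
          rep(tmpl + drift, each = nSnip), nSnip) +
          matrix(stats::rnorm(nSnip * params$nSamples, 0,
                              params$snippetNoiseSd), nSnip)
      }
    }
    units[[u]] <- unitRecording(sprintf("u%02d_%s", u, regions[u]),
                                regions[u], st, wf)
  }
  units
}

#' Write a synthetic dataset fixture to disk
#'
#' Profiles: \code{tiny} (2 sessions, 1 animal, 4 units; completes in
#' seconds), \code{default} (the full 9-session design: 20 behavioral
#' animals of which 7 carry recordings with 18 M1 + 10 DS units each), and
#' \code{control_task} (count-target schedule: exactly 4 presses
#' reinforced).
#'
#' @param profile fixture profile name.
#' @param dir output directory.
#' @param seed integer master seed (substreams per animal).
#' @param force overwrite an existing directory.
#' @return Invisibly, \code{dir}.
#' @export
makeFixture <- function(profile = c("tiny", "default", "control_task"),
                        dir, seed = 1L, force = FALSE) {
  profile <- match.arg(profile)
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("output directory exists; use force = TRUE to overwrite")
  dir.create(file.path(dir, "events"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "spikes"), recursive = TRUE,
             showWarnings = FALSE)
  cfg <- switch(profile,
    tiny = list(nAnimals = 1L, nRecorded = 1L, nSessions = 2L,
                nM1 = 3L, nDS = 1L, duration = 200),
    default = list(nAnimals = 20L, nRecorded = 7L, nSessions = 9L,
                   nM1 = 18L, nDS = 10L, duration = 600),
    control_task = list(nAnimals = 2L, nRecorded = 0L, nSessions = 2L,
                        nM1 = 0L, nDS = 0L, duration = 300))
  ns <- cfg$nSessions
  idx <- round(seq(1, 9, length.out = ns))
  base <- behaviorGenParams()
  bp <- behaviorGenParams(
    nSessions = ns,
    targetFrequencies = base$targetFrequencies[idx],
    sequencesPerMin = base$sequencesPerMin[idx],
    lengthMean = base$lengthMean[idx],
    lengthDispersion = base$lengthDispersion[idx],
    ipiMedian = base$ipiMedian[idx],
    ipiLogSd = base$ipiLogSd[idx],
    sessionDuration = cfg$duration)
  animals <- sprintf("A%02d", seq_len(cfg$nAnimals))
  files <- list(events = list(), spikes = list(), waveforms = list())
  schedules <- vector("list", ns)
  for (ai in seq_along(animals)) {
    a <- animals[ai]
    beh <- generateBehavior(bp, a, seed = .substream(seed, 100L + ai))
    if (profile == "control_task") {
      beh$events <- lapply(beh$events, function(ev) {
        sch <- scheduleEntry("count_target", requiredCount = 4L)
        seg <- segmentSequences(pressTimes(ev), headEntryTimes(ev))
        lab <- labelReinforcement(seg$sequences, sch)
        rf <- unlist(Map(function(p, h) p[h], seg$sequences,
                         lab$hitIndices), use.names = FALSE)
        sessionEvents(animalId(ev), sessionIndex(ev), sch,
                      pressTimes(ev), headEntryTimes(ev),
                      sort(rf %||% numeric()), sessionDuration(ev))
      })
    }
    evPaths <- character(ns)
    for (s in seq_len(ns)) {
      evPaths[s] <- file.path("events", sprintf("%s_s%d.csv", a, s))
      writeSessionEvents(beh$events[[s]], file.path(dir, evPaths[s]))
      schedules[[s]] <- .scheduleToList(schedule(beh$events[[s]]))
    }
    files$events[[a]] <- as.list(evPaths)
    if (ai <= cfg$nRecorded && cfg$nM1 + cfg$nDS > 0L) {
      np <- neuralGenParams(nUnitsM1 = cfg$nM1, nUnitsDS = cfg$nDS,
                            nSessions = ns,
                            gainLogSd = seq(0.9, 0.2, length.out = ns))
      units <- generateSpikes(beh, np, seed = .substream(seed, 200L + ai))
      spPath <- file.path("spikes", sprintf("%s_spikes.csv", a))
      wfDir <- file.path("spikes", sprintf("%s_waveforms", a))
      writeUnitRecordings(units, file.path(dir, spPath),
                          file.path(dir, wfDir))
      files$spikes[[a]] <- spPath
      files$waveforms[[a]] <- wfDir
    }
  }
  manifest <- list(
    animals = as.list(animals),
    sessions = lapply(seq_len(ns), function(s)
      c(list(index = s, duration_s = cfg$duration), schedules[[s]])),
    files = files)
  writeManifest(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
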