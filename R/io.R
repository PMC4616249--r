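## On-disk formats
##  events:   CSV with columns time_s,event_type (press|head_entry|reinforcer)
##  spikes:   CSV with columns unit_id,region,session_index,spike_time_s
##  waveforms: one header-less CSV matrix per (unit, session),
##             named <unit_id>_s<session_index>.csv
##  manifest: YAML listing animals, session schedules, durations, file paths

.EVENT_TYPES <- c("press", "head_entry", "reinforcer")

.collapseDuplicates <- function(times, what) {
  times <- sort(times)
  dup <- duplicated(times)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate %s timestamp(s)", sum(dup), what),
            call. = FALSE)
    times <- times[!dup]
  }
  times
}

#' Read one session's event log
#'
#' Parses a delimited event table (columns \code{time_s}, \code{event_type})
#' into a \linkS4class{SessionEvents}. Rows may appear in any order;
#' duplicate timestamps within an event type are collapsed with a warning.
#' Schedule metadata comes from the caller (normally the dataset manifest).
#'
#' @param path CSV file path.
#' @param animalId,sessionIndex session identity.
#' @param schedule a \linkS4class{ScheduleEntry}.
#' @param sessionDuration session length in seconds; defaults to the latest
#'   event time when not supplied by a manifest.
#' @return A \linkS4class{SessionEvents}.
#' @export
readSessionEvents <- function(path, animalId = "unknown", sessionIndex = 1L,
                              schedule = scheduleEntry(targetFrequency = 0),
                              sessionDuration = NA_real_) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "event_type")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("event file %s missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (nrow(tab)) {
    t <- suppressWarnings(as.numeric(tab$time_s))
    bad <- which(is.na(t))
    if (length(bad))
      stop(sprintf("non-numeric time_s at row %d of %s", bad[1L], path))
    bad <- which(t < 0)
    if (length(bad))
      stop(sprintf("negative time_s at row %d of %s", bad[1L], path))
    badType <- which(!tab$event_type %in% .EVENT_TYPES)
    if (length(badType))
      stop(sprintf("unknown event_type '%s' at row %d of %s",
                   tab$event_type[badType[1L]], badType[1L], path))
    tab$time_s <- t
  }
  pick <- function(type) .collapseDuplicates(
    tab$time_s[tab$event_type == type], type)
  press <- pick("press")
  he <- pick("head_entry")
  rf <- pick("reinforcer")
  if (is.na(sessionDuration))
    sessionDuration <- max(c(press, he, rf, 0))
  sessionEvents(animalId, sessionIndex, schedule, press, he, rf,
                max(sessionDuration, 1e-9))
}

#' Write one session's event log
#'
#' Inverse of \code{\link{readSessionEvents}}: the round trip reproduces
#' event times to within 1e-6 s.
#'
#' @param events a \linkS4class{SessionEvents}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeSessionEvents <- function(events, path) {
  tab <- data.frame(
    time_s = c(pressTimes(events), headEntryTimes(events),
               reinforcerTimes(events)),
    event_type = rep(.EVENT_TYPES,
                     c(length(pressTimes(events)),
                       length(headEntryTimes(events)),
                       length(reinforcerTimes(events)))))
  tab <- tab[order(tab$time_s), , drop = FALSE]
  tab$time_s <- sprintf("%.6f", tab$time_s)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sorted-unit spike times and waveform snippets
#'
#' @param spikePath CSV with columns \code{unit_id}, \code{region},
#'   \code{session_index}, \code{spike_time_s}.
#' @param waveformDir optional directory of header-less CSV matrices named
#'   \code{<unit_id>_s<session_index>.csv}; units without files get empty
#'   waveform lists.
#' @return A list of \linkS4class{UnitRecording}, one per unit, sessions
#'   ordered by index.
#' @export
readUnitRecordings <- function(spikePath, waveformDir = NULL) {
  tab <- read.csv(spikePath, stringsAsFactors = FALSE)
  need <- c("unit_id", "region", "session_index", "spike_time_s")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("spike file missing column(s): %s",
                 paste(miss, collapse = ", ")))
  bad <- which(!tab$region %in% .REGIONS)
  if (length(bad))
    stop(sprintf("unknown region '%s' at row %d (must be M1 or DS)",
                 tab$region[bad[1L]], bad[1L]))
  out <- list()
  for (uid in unique(tab$unit_id)) {
    sub <- tab[tab$unit_id == uid, , drop = FALSE]
    sessions <- sort(unique(sub$session_index))
    st <- lapply(sessions, function(s)
      .collapseDuplicates(sub$spike_time_s[sub$session_index == s],
                          sprintf("spike (%s s%d)", uid, s)))
    names(st) <- as.character(sessions)
    wf <- list()
    if (!is.null(waveformDir)) {
      for (s in sessions) {
        f <- file.path(waveformDir, sprintf("%s_s%d.csv", uid, s))
        if (file.exists(f))
          wf[[as.character(s)]] <- as.matrix(
            read.csv(f, header = FALSE))
      }
    }
    out[[uid]] <- unitRecording(uid, sub$region[1L], st, wf)
  }
  out
}

#' Write unit recordings to the spike/waveform on-disk format
#'
#' @param units list of \linkS4class{UnitRecording}.
#' @param spikePath output CSV path for spike times.
#' @param waveformDir output directory for snippet matrices (created);
#'   omit to skip waveform output.
#' @return Invisibly, \code{spikePath}.
#' @export
writeUnitRecordings <- function(units, spikePath, waveformDir = NULL) {
  rows <- lapply(units, function(u) {
    st <- spikeTimes(u)
    do.call(rbind, lapply(names(st), function(s)
      if (length(st[[s]]))
        data.frame(unit_id = unitId(u), region = region(u),
                   session_index = as.integer(s),
                   spike_time_s = sprintf("%.6f", st[[s]]))))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(unit_id = character(), region = character(),
                      session_index = integer(), spike_time_s = character())
  write.csv(tab, spikePath, row.names = FALSE, quote = FALSE)
  if (!is.null(waveformDir)) {
    dir.create(waveformDir, recursive = TRUE, showWarnings = FALSE)
    for (u in units) {
      wf <- waveforms(u)
      for (s in names(wf))
        write.table(wf[[s]],
                    file.path(waveformDir,
                              sprintf("%s_s%s.csv", unitId(u), s)),
                    sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(spikePath)
}

.scheduleToList <- function(sch) {
  list(mode = sch@mode,
       target_frequency = if (is.na(sch@targetFrequency)) NULL
                          else sch@targetFrequency,
       required_count = if (is.na(sch@requiredCount)) NULL
                        else sch@requiredCount)
}

.scheduleFromList <- function(x) {
  scheduleEntry(mode = x$mode,
                targetFrequency = if (is.null(x$target_frequency)) NA_real_
                                  else x$target_frequency,
                requiredCount = if (is.null(x$required_count)) NA_integer_
                                else as.integer(x$required_count))
}

#' Write a dataset manifest
#'
#' The manifest is a YAML file listing animals, the ordered session
#' schedules with durations, and relative file paths for event logs and
#' spike/waveform files. All other readers take their metadata from it.
#'
#' @param manifest a list as produced by \code{\link{makeFixture}} /
#'   \code{\link{readManifest}}.
#' @param path output YAML path.
#' @return Invisibly, \code{path}.
#' @export
writeManifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path manifest YAML path.
#' @return The manifest list; session indices are checked to be contiguous
#'   from 1.
#' @export
readManifest <- function(path) {
  m <- yaml::read_yaml(path)
  idx <- vapply(m$sessions, function(s) as.integer(s$index), 1L)
  if (!identical(idx, seq_along(idx)))
    stop("manifest session indices must be contiguous starting at 1")
  m
}

#' Load a full dataset directory
#'
#' Reads the manifest then every referenced event log and spike file.
#'
#' @param dir dataset directory containing \code{manifest.yaml}.
#' @return A list with elements \code{manifest}, \code{events} (nested list
#'   animal -> session -> \linkS4class{SessionEvents}) and \code{units}
#'   (list animal -> list of \linkS4class{UnitRecording}).
#' @export
readDataset <- function(dir) {
  m <- readManifest(file.path(dir, "manifest.yaml"))
  schedules <- lapply(m$sessions, .scheduleFromList)
  events <- list()
  units <- list()
  for (a in m$animals) {
    ev <- list()
    for (s in seq_along(m$sessions)) {
      f <- file.path(dir, m$files$events[[a]][[s]])
      ev[[s]] <- readSessionEvents(
        f, animalId = a, sessionIndex = s, schedule = schedules[[s]],
        sessionDuration = m$sessions[[s]]$duration_s)
    }
    events[[a]] <- ev
    sp <- m$files$spikes[[a]]
    if (!is.null(sp)) {
      wd <- m$files$waveforms[[a]]
      units[[a]] <- readUnitRecordings(
        file.path(dir, sp),
        if (is.null(wd)) NULL else file.path(dir, wd))
    }
  }
  list(manifest = m, events = events, units = units)
}
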