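test_that("segmentation recovers the generated bout partition exactly", {
  for (s in c(3, 17)) {
    beh <- generateBehavior(tinyBehaviorParams(), seed = s)
    truth <- beh$truth$sequences
    for (i in seq_along(beh$events)) {
      tab <- sessionSequences(beh$events[[i]])
      tr <- truth[truth$session == i, ]
      expect_equal(nrow(tab), nrow(tr))
      expect_equal(sort(tab$start_s), sort(tr$start_s), tolerance = 1e-9)
      expect_equal(sort(tab$length), sort(tr$length))
      expect_equal(attr(tab, "isolatedCount"), 0L)
    }
  }
})

test_that("reinforcer events coincide with hit-completing presses", {
  beh <- generateBehavior(tinyBehaviorParams(), seed = 8)
  for (ev in beh$events) {
    rf <- reinforcerTimes(ev)
    if (!length(rf)) next
    expect_true(all(vapply(rf, function(t)
      any(abs(pressTimes(ev) - t) < 1e-3), TRUE)))
  }
})

test_that("risky IPI parameters trigger the truncation warning", {
  expect_warning(
    behaviorGenParams(ipiMedian = c(1.5, rep(0.3, 8))),
    "P\\(IPI")
  expect_silent(behaviorGenParams())
})

test_that("raising the check probability raises measured check rates", {
  pLow <- tinyBehaviorParams(); pLow$pCheck <- 0.1
  pHigh <- tinyBehaviorParams(); pHigh$pCheck <- 0.8
  rate <- function(params, s) {
    beh <- generateBehavior(params, seed = s)
    mean(vapply(beh$events, function(ev)
      length(headEntryTimes(ev)) /
        max(1L, nrow(sessionSequences(ev))), 1))
  }
  lows <- vapply(1:5, function(s) rate(pLow, s), 1)
  highs <- vapply(1:5, function(s) rate(pHigh, s), 1)
  expect_true(all(highs > lows))
})

test_that("mean firing rate stays within 5% of lambda in every session", {
  beh <- generateBehavior(behaviorGenParams(), seed = 21)
  units <- generateSpikes(beh, neuralGenParams(nUnitsM1 = 4, nUnitsDS = 2,
                                               lambda = 6), seed = 21)
  for (s in 1:9) {
    rates <- vapply(units, function(u) {
      st <- spikeTimes(u)[[as.character(s)]]
      length(st) / sessionDuration(beh$events[[s]])
    }, 1)
    expect_equal(mean(rates), 6, tolerance = 0.05)
  }
})

test_that("uncoupled constant-gain units show no session FF trend", {
  set.seed(70)
  rhos <- vapply(1:8, function(s) {
    beh <- generateBehavior(behaviorGenParams(), seed = 100 + s)
    units <- generateSpikes(beh, neuralGenParams(
      nUnitsM1 = 3, nUnitsDS = 0, beta = 0,
      gainLogSd = rep(0.5, 9)), seed = 100 + s)
    sq <- beh$truth$sequences
    seqTabs <- lapply(1:9, function(i) sq[sq$session == i, , drop = FALSE])
    tab <- spikeVariabilityTable(units, seqTabs)
    m <- aggregate(ff_sequence ~ session, tab, mean)
    cor(m$session, m$ff_sequence, method = "spearman")
  }, 1)
  # mean Spearman rho across seeds should be near zero under the null
  expect_lt(abs(mean(rhos)), 2.5 * sd(rhos) / sqrt(length(rhos)) + 0.25)
})

test_that("fixtures are deterministic and honor profiles", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  makeFixture("tiny", d1, seed = 9)
  makeFixture("tiny", d2, seed = 9)
  f <- file.path("events", list.files(file.path(d1, "events")))
  for (p in f)
    expect_identical(readLines(file.path(d1, p)),
                     readLines(file.path(d2, p)))
  expect_error(makeFixture("tiny", d1, seed = 9), "force")

  d3 <- withr::local_tempdir()
  makeFixture("control_task", d3, seed = 9, force = TRUE)
  m <- readManifest(file.path(d3, "manifest.yaml"))
  expect_equal(m$sessions[[1]]$mode, "count_target")
  expect_equal(m$sessions[[1]]$required_count, 4L)
  ds <- readDataset(d3)
  ev <- ds$events[[1]][[1]]
  tab <- sessionSequences(ev)
  expect_true(all(tab$reinforced == (tab$length == 4L)))
})
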