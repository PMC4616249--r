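test_that("window rates use half-open windows", {
  expect_equal(windowRate(c(1.0, 1.5, 2.0), c(1, 2)), 2)
  expect_equal(windowRate(numeric(), c(0, 1)), 0)
  expect_equal(windowRate(c(0.5), c(0.5, 1.5)), 1)  # spike at a included
  expect_error(windowRate(1, c(2, 2)), "b > a")
})

test_that("trial-rate Fano factor and modulation ratio behave as defined", {
  expect_equal(unitFanoAcrossTrials(c(2, 2, 2)), 0)
  expect_equal(unitFanoAcrossTrials(c(1, 2, 3)), 0.5)
  expect_true(is.na(unitFanoAcrossTrials(c(0, 0))))
  expect_error(unitFanoAcrossTrials(2), "at least 2")

  expect_equal(modulationRatio(2, 1), 1)
  expect_equal(modulationRatio(1, 2), -0.5)
  expect_equal(modulationRatio(3, 3), 0)
  expect_true(is.na(modulationRatio(1, 0)))
  # invariant to common rescaling
  set.seed(30)
  for (i in 1:10) {
    s <- runif(1, 0.5, 4); b <- runif(1, 0.5, 4); c0 <- runif(1, 0.1, 10)
    expect_equal(modulationRatio(c0 * s, c0 * b), modulationRatio(s, b))
  }
})

test_that("trial windows have fixed extents and drop pre-session trials", {
  tab <- data.frame(start_s = c(1, 10), duration_s = c(0.5, 1))
  w <- trialWindows(tab)
  expect_equal(nrow(w), 1L)  # first trial's baseline would start at -4 s
  expect_equal(w$base_end - w$base_start, 3)
  expect_equal(w$first_flank_end - w$first_flank_start, 1)
  expect_equal(w$seq_start, 10)
  expect_equal(w$seq_end, 11)
})

test_that("PETH bins pool spikes at 20 ms / 1 ms and conserve counts", {
  # single trial, spikes at -5 ms and +5 ms: the bin centered at 0 covers
  # [-10, 10) ms and must read 2 / (1 x 0.020) = 100 Hz
  p <- buildPETH(list(c(9.995, 10.005)), 10)
  i0 <- which(abs(binCenters(p)) < 1e-9)
  expect_length(i0, 1L)
  expect_equal(rates(p)[i0], 100)

  expect_true(all(rates(buildPETH(list(numeric()), 10)) == 0))

  # stationary unit: flat PETH at the true rate and count conservation
  set.seed(31)
  align <- alignGrid(150)
  trials <- lapply(align, function(t0) t0 + sort(runif(rpois(1, 120), -7, 5)) )
  p <- buildPETH(trials, align)
  expect_equal(baselineMean(p), 10, tolerance = 0.1)
  expect_equal(mean(rates(p)), 10, tolerance = 0.1)
  nInRange <- sum(mapply(function(st, t0)
    sum(st - t0 >= -5 & st - t0 < 2), trials, align))
  # each spike enters ~20 overlapping bins: sum(rates) * step ~ n / trials
  expect_equal(sum(rates(p)) * 0.001 * length(align), nInRange,
               tolerance = 0.01)
})

test_that("modulation classifier detects steps and silencing, not nulls", {
  set.seed(32)
  align <- alignGrid(80)
  up <- classifyTaskRelated(
    buildPETH(lapply(align, stepTrial, gain = 3), align))
  expect_equal(modulation(up), "positive")
  down <- classifyTaskRelated(
    buildPETH(lapply(align, stepTrial, gain = 0, stepDur = 0.3), align))
  expect_equal(modulation(down), "negative")
  flat <- classifyTaskRelated(
    buildPETH(lapply(align, stepTrial, gain = 1), align))
  expect_equal(modulation(flat), "none")
})

test_that("paired sequence-vs-baseline test flags rate-modulated units", {
  set.seed(33)
  align <- alignGrid(60)
  trials <- lapply(align, stepTrial, gain = 3)
  p <- buildPETH(trials, align)
  seqR <- mapply(function(st, t0) windowRate(st, c(t0, t0 + 0.5)),
                 trials, align)
  baseR <- mapply(function(st, t0) windowRate(st, c(t0 - 5, t0 - 2)),
                  trials, align)
  p <- classifyTaskRelated(p, seqR, baseR)
  expect_true(p@sequenceRelated)
  p0 <- classifyTaskRelated(p, NULL, NULL)
  expect_true(is.na(p0@sequenceRelated))
})

test_that("per-unit session statistics assemble into the modulation table", {
  set.seed(34)
  bp <- tinyBehaviorParams()
  beh <- generateBehavior(bp, seed = 5)
  units <- generateSpikes(beh, neuralGenParams(
    nUnitsM1 = 2L, nUnitsDS = 1L, nSessions = 3L,
    gainLogSd = c(0.8, 0.5, 0.2)), seed = 5)
  sq <- beh$truth$sequences
  seqTabs <- lapply(1:3, function(s) sq[sq$session == s, , drop = FALSE])
  tab <- spikeVariabilityTable(units, seqTabs)
  expect_equal(nrow(tab), 9L)
  expect_true(all(tab$ff_sequence >= 0, na.rm = TRUE))
  expect_equal(tab$ff_modulation,
               (tab$ff_sequence - tab$ff_baseline) / tab$ff_baseline,
               tolerance = 1e-12)
  fl <- flankFano(units[[1]], seqTabs[[2]], 2L)
  expect_true(is.finite(fl$ffFirst) && is.finite(fl$ffLast))
})
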