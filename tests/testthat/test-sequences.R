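test_that("segmentation splits on >2 s gaps and on head entries", {
  seg <- segmentSequences(c(0, 0.3, 0.6, 3.6, 3.9))
  expect_equal(seg$sequences, list(c(0, 0.3, 0.6), c(3.6, 3.9)))
  expect_equal(seg$isolatedCount, 0L)

  seg <- segmentSequences(c(0, 0.5, 1.0), headEntryTimes = 0.7)
  expect_equal(seg$sequences, list(c(0, 0.5)))
  expect_equal(seg$isolatedCount, 1L)

  expect_equal(segmentSequences(numeric()),
               list(sequences = list(), isolatedCount = 0L))
  # a gap of exactly the threshold does not split (strict >)
  seg <- segmentSequences(c(0, 2.0))
  expect_equal(seg$sequences, list(c(0, 2.0)))
  expect_error(segmentSequences(c(1, 0.5)), "sorted")
})

test_that("segmentation satisfies the partition property on random input", {
  set.seed(10)
  for (i in 1:25) {
    press <- sort(runif(sample(0:40, 1), 0, 60))
    press <- press[!duplicated(press)]
    he <- sort(runif(sample(0:10, 1), 0, 60))
    seg <- segmentSequences(press, he)
    expect_equal(sum(lengths(seg$sequences)) + seg$isolatedCount,
                 length(press))
    for (p in seg$sequences) {
      expect_true(all(diff(p) <= 2))
      expect_false(any(he > p[1L] & he < p[length(p)]))
    }
  }
})

test_that("sequence features match hand-computed values", {
  f <- sequenceFeatures(c(0, 0.2, 0.4, 0.8))
  expect_equal(f$frequency, 3.75)
  expect_equal(f$duration, 0.8)
  expect_equal(f$length, 4L)
  f <- sequenceFeatures(c(0, 1.0))
  expect_equal(f$frequency, 1.0)
  expect_equal(f$duration, 1.0)
  f <- sequenceFeatures(c(0, 0.44, 0.88))
  expect_equal(f$frequency, 1 / 0.44)
  expect_error(sequenceFeatures(0.5), "fewer than 2")
})

test_that("covert-target scan matches hand traces with and without reset", {
  expect_equal(detectCovertTargets(c(0.2, 0.2, 0.2, 0.5), 0.660), 4L)
  expect_equal(detectCovertTargets(c(0.3, 0.3, 0.3), 0.660), integer())
  expect_equal(detectCovertTargets(rep(0.1, 7), 0.660), c(4L, 7L))
  expect_equal(detectCovertTargets(rep(0.1, 7), 0.660, resetOnHit = FALSE),
               4:8)
  expect_equal(detectCovertTargets(numeric(), 0.660), integer())
  expect_error(detectCovertTargets(c(0.1, 0.1, 0.1), 0), "positive")
})

test_that("non-reset scan equals brute-force window enumeration", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(0:20, 1)
    ipis <- round(runif(n, 0.05, 1.2), 3)
    bound <- runif(1, 0.2, 2)
    expect_identical(detectCovertTargets(ipis, bound, resetOnHit = FALSE),
                     bruteForceTargets(ipis, bound))
  }
})

test_that("hit counts are monotone in the bound and in the target", {
  set.seed(12)
  for (i in 1:20) {
    ipis <- runif(12, 0.05, 0.8)
    b1 <- runif(1, 0.1, 1); b2 <- b1 + runif(1, 0, 1)
    expect_lte(length(detectCovertTargets(ipis, b1, resetOnHit = FALSE)),
               length(detectCovertTargets(ipis, b2, resetOnHit = FALSE)))
    # reinforced under target f implies reinforced under any f' < f
    p <- cumsum(c(0, ipis))
    f <- runif(1, 1, 6); fLow <- f * runif(1, 0.2, 1)
    labHigh <- labelReinforcement(list(p), scheduleEntry(targetFrequency = f))
    labLow <- labelReinforcement(list(p),
                                 scheduleEntry(targetFrequency = fLow))
    if (labHigh$reinforced) expect_true(labLow$reinforced)
  }
})

test_that("reinforcement labeling follows the schedule mode", {
  seqs <- list(c(0, 0.2, 0.4, 0.6), c(0, 1, 2, 3, 4))
  lab <- labelReinforcement(seqs, scheduleEntry(targetFrequency = 4.5))
  expect_equal(lab$reinforced, c(TRUE, FALSE))
  expect_equal(lab$hitIndices[[1]], 4L)

  lab <- labelReinforcement(seqs, scheduleEntry("count_target",
                                                requiredCount = 4L))
  expect_equal(lab$reinforced, c(TRUE, FALSE))
  lab <- labelReinforcement(seqs, scheduleEntry("continuous_reinforcement"))
  expect_true(all(lab$reinforced))
  expect_error(scheduleEntry("count_target", requiredCount = 1L),
               "requiredCount")
})

test_that("session summary computes target distance and spread as stated", {
  # two 3-IPI windows summing 0.9 and 0.7 s against the 0.66-s bound:
  # sequence with IPIs 0.5, 0.2, 0.2, 0.3 gives windows 0.9 and 0.7
  ev <- sessionEvents("m", 9L, scheduleEntry(targetFrequency = 4.5),
                      pressTimes = cumsum(c(1, 0.5, 0.2, 0.2, 0.3)),
                      sessionDuration = 60)
  s <- sessionSummary(ev, endTargetBound = 0.66)
  expect_equal(s$distance_to_end_target, mean(c(0.24, 0.04)))
  expect_equal(s$spread_around_end_target, sqrt((0.24^2 + 0.04^2) / 2))

  # all windows exactly at the bound
  ev <- sessionEvents("m", 9L, scheduleEntry(targetFrequency = 4.5),
                      pressTimes = cumsum(c(1, rep(0.22, 4))),
                      sessionDuration = 60)
  s <- sessionSummary(ev, endTargetBound = 0.66)
  expect_equal(s$distance_to_end_target, 0)
  expect_equal(s$spread_around_end_target, 0)

  # 10 presses, 8 in sequences
  ev <- sessionEvents("m", 1L, scheduleEntry(targetFrequency = 0),
                      pressTimes = c(1, 1.5, 2, 2.5, 10, 10.5, 11, 11.5,
                                     20, 30),
                      sessionDuration = 60)
  s <- sessionSummary(ev)
  expect_equal(s$pct_presses_in_sequences, 80)
  expect_equal(s$isolated_presses, 2L)

  # no 3-IPI window: distance and spread are missing, not zero
  ev <- sessionEvents("m", 1L, scheduleEntry(targetFrequency = 0),
                      pressTimes = c(1, 1.5), sessionDuration = 60)
  s <- sessionSummary(ev)
  expect_true(is.na(s$distance_to_end_target))
  expect_true(is.na(s$spread_around_end_target))
})

test_that("magazine-check probabilities follow the next-event rule", {
  # hits complete at presses 1.0 and 2.0; head entry at 1.1 precedes the
  # next press after the first hit only
  press <- c(0.4, 0.6, 0.8, 1.0, 1.5, 1.7, 1.9, 2.0, 2.4)
  ev <- sessionEvents("m", 9L, scheduleEntry(targetFrequency = 4.5),
                      pressTimes = press, headEntryTimes = 1.1,
                      sessionDuration = 60)
  tab <- sessionSequences(ev)
  hits <- unlist(Map(function(p, h) p[h], attr(tab, "pressTimes"),
                     attr(tab, "hitIndices")))
  expect_equal(sort(hits), c(1.0, 2.0))
  pr <- magazineCheckProbabilities(ev, tab)
  expect_equal(pr$afterSuccess, 0.5)
  expect_equal(pr$afterReinforcedPress, 0.5)
  expect_equal(pr$afterNonReinforcedPress, 0)

  # no head entries at all: probabilities 0 (hits exist)
  ev0 <- sessionEvents("m", 9L, scheduleEntry(targetFrequency = 4.5),
                       pressTimes = press, sessionDuration = 60)
  pr0 <- magazineCheckProbabilities(ev0)
  expect_equal(pr0$afterSuccess, 0)

  # every press immediately followed by a head entry: probabilities 1
  ev1 <- sessionEvents("m", 9L, scheduleEntry(targetFrequency = 0),
                       pressTimes = c(1, 4, 7),
                       headEntryTimes = c(1.1, 4.1, 7.1),
                       sessionDuration = 60)
  pr1 <- magazineCheckProbabilities(ev1)
  expect_equal(pr1$afterNonReinforcedPress, 1)
})
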