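test_that("trace alignment matches windows by session and center index", {
  a <- new("FanoTrace", windowSize = 5L, values = c(1, 2, 3),
           centerIndices = c(3L, 4L, 5L), sessionIndices = c(1L, 1L, 1L))
  b <- new("FanoTrace", windowSize = 5L, values = c(9, 8, 7),
           centerIndices = c(3L, 4L, 5L), sessionIndices = c(1L, 1L, 1L))
  expect_equal(nrow(alignTraces(a, b)), 3L)
  b2 <- new("FanoTrace", windowSize = 5L, values = c(8, 7),
            centerIndices = c(4L, 5L), sessionIndices = c(1L, 1L))
  al <- alignTraces(a, b2)
  expect_equal(al$center, c(4L, 5L))
  expect_equal(al$y, c(8, 7))
  b3 <- new("FanoTrace", windowSize = 5L, values = 1,
            centerIndices = 9L, sessionIndices = 2L)
  expect_equal(nrow(alignTraces(a, b3)), 0L)
  b4 <- new("FanoTrace", windowSize = 7L, values = 1,
            centerIndices = 4L, sessionIndices = 1L)
  expect_error(alignTraces(a, b4), "window size")
})

test_that("critical r matches the inverted correlation test", {
  # oracle: smallest |r| rejected by cor.test at alpha, found numerically
  oracle <- function(n, alpha = 0.05) {
    uniroot(function(r)
      stats::pt(r * sqrt((n - 2) / (1 - r^2)), n - 2,
                lower.tail = FALSE) * 2 - alpha,
      c(1e-6, 1 - 1e-6), tol = 1e-12)$root
  }
  expect_equal(criticalR(20), 0.444, tolerance = 1e-3)
  for (n in c(5, 10, 20, 50))
    expect_equal(criticalR(n), oracle(n), tolerance = 1e-8)
  expect_lt(criticalR(13), criticalR(12))
  expect_lt(criticalR(3, alpha = 0.999), 0.05)
  expect_error(criticalR(2), "n >= 3")
})

test_that("Fisher-z averaging is idempotent, symmetric and matches hand math", {
  expect_equal(fisherZAverage(c(0.5, 0.5)), 0.5)
  expect_equal(fisherZAverage(c(0, 0.8)), tanh(atanh(0.8) / 2))
  expect_equal(fisherZAverage(c(0, 0.8)), 0.5, tolerance = 1e-4)
  expect_equal(fisherZAverage(c(-0.6, 0.6)), 0)
  expect_warning(out <- fisherZAverage(c(1, 0)), "clipping")
  expect_lt(out, 1)
})

test_that("session correlations use the smallest-session critical r", {
  set.seed(50)
  x <- rnorm(40); y <- x + rnorm(40, 0, 0.3)
  pairs <- data.frame(session = rep(1:2, c(30, 10)), center = 1:40,
                      x = x, y = y)
  tab <- traceCorrelations(pairs)
  expect_equal(unique(tab$critical_r), criticalR(10))
  expect_true(all(tab$significant))
  expect_equal(attr(tab, "pooled_r"), fisherZAverage(tab$r))
})

test_that("independent traces are declared significant at about alpha", {
  set.seed(51)
  hits <- 0L; total <- 0L
  for (i in 1:150) {
    pairs <- data.frame(session = rep(1:3, each = 12), center = 1:36,
                        x = rnorm(36), y = rnorm(36))
    tab <- traceCorrelations(pairs)
    hits <- hits + sum(tab$significant)
    total <- total + nrow(tab)
  }
  expect_lt(hits / total, 0.05 + 2.5 * sqrt(0.05 * 0.95 / total))
})

test_that("coupled gains produce frequency-specific FF correlations", {
  set.seed(52)
  beh <- generateBehavior(behaviorGenParams(), seed = 11)
  units <- generateSpikes(beh, neuralGenParams(nUnitsM1 = 6, nUnitsDS = 3,
                                               beta = 0.8), seed = 11)
  cr <- couplingReport(beh$truth$sequences, units)
  nsig <- vapply(cr, function(t) sum(t$significant, na.rm = TRUE), 1L)
  expect_gte(nsig[["M1_ff_x_frequency_ff"]], 3L)
  expect_lte(nsig[["M1_ff_x_duration_ff"]], 2L)
  # shared behavioral gain drive couples the two regions
  expect_gte(nsig[["M1_ff_x_DS_ff"]], 3L)
  expect_gt(attr(cr[["M1_ff_x_frequency_ff"]], "overall_r"), 0.2)
})
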