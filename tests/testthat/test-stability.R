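test_that("pooled axes are orthonormal with deterministic signs", {
  set.seed(40)
  tmpl <- sin(seq(0, 3 * pi, length.out = 16))
  wf <- list(`1` = wfCloud(40, tmpl), `2` = wfCloud(40, tmpl))
  pca <- pooledPrincipalAxes(wf)
  expect_equal(colSums(pca$axes^2), c(1, 1), ignore_attr = TRUE)
  expect_equal(sum(pca$axes[, 1] * pca$axes[, 2]), 0, tolerance = 1e-10)
  expect_gte(pca$axes[which.max(abs(pca$axes[, 1])), 1], 0)
  # permutation invariance
  X <- do.call(rbind, wf)
  pca2 <- pooledPrincipalAxes(list(X[sample(nrow(X)), ]))
  expect_equal(pca$axes, pca2$axes, tolerance = 1e-8)
})

test_that("rank-1 clouds put all variance on PC1 and degenerate input errors", {
  line <- outer(seq(-1, 1, length.out = 20), c(1, 2, 3))
  pca <- pooledPrincipalAxes(list(line), nAxes = 1L)
  expect_equal(pca$varExplained[1], 1)
  expect_error(pooledPrincipalAxes(list(line)), "rank-deficient")
  expect_error(pooledPrincipalAxes(list(matrix(1, 1, 4))), "at least 2")
})

test_that("session cluster statistics recover injected dispersion", {
  set.seed(41)
  axes <- diag(4)[, 1:2]
  cloud <- cbind(rnorm(4000, 0, 1), rnorm(4000, 0, 2),
                 rnorm(4000, 0, 0.1), rnorm(4000, 0, 0.1))
  st <- sessionClusterStats(cloud, axes, rep(0, 4))
  expect_equal(st$sd, c(1, 2), tolerance = 0.06, ignore_attr = TRUE)
  same <- matrix(5, 3, 4)
  st0 <- sessionClusterStats(same, axes, colMeans(same))
  expect_equal(st0$sd, c(0, 0), ignore_attr = TRUE)
})

test_that("stability criterion passes stationary units and flags drift", {
  set.seed(42)
  tmpl <- 80 * sin(seq(0, 3 * pi, length.out = 24))
  stationary <- unitRecording("s", "M1",
    list(`1` = c(0.1, 0.2), `2` = c(0.1, 0.2), `3` = c(0.1, 0.2)),
    list(`1` = wfCloud(150, tmpl, 4), `2` = wfCloud(150, tmpl, 4),
         `3` = wfCloud(150, tmpl, 4)))
  res <- assessStability(stationary)
  expect_true(res$overallStable)
  expect_equal(nrow(res$table), 4L)

  # displace session 2 by ~3 cluster SDs along PC1
  w1 <- wfCloud(150, tmpl, 4)
  pca <- pooledPrincipalAxes(list(w1))
  sd1 <- sessionClusterStats(w1, pca$axes, pca$center)$sd[1]
  w2 <- w1 + matrix(rep(3 * sd1 * pca$axes[, 1], each = 150), 150)
  drifted <- unitRecording("d", "M1",
    list(`1` = c(0.1, 0.2), `2` = c(0.1, 0.2)),
    list(`1` = w1, `2` = w2))
  expect_false(assessStability(drifted)$overallStable)

  # displacement of exactly 1.96 SD passes (inclusive bound)
  shifted <- w1 + matrix(rep(1.96 * sd1 * pca$axes[, 1], each = 150), 150)
  boundary <- unitRecording("b", "M1",
    list(`1` = c(0.1, 0.2), `2` = c(0.1, 0.2)),
    list(`1` = w1, `2` = shifted))
  resB <- assessStability(boundary)
  pc1 <- resB$table[resB$table$pc == 1, ]
  expect_equal(pc1$displacement, pc1$bound, tolerance = 0.02)
  expect_true(pc1$pass)
})

test_that("the decision is invariant to global waveform scaling", {
  set.seed(43)
  tmpl <- 60 * sin(seq(0, 2 * pi, length.out = 20))
  w <- list(`1` = wfCloud(80, tmpl, 5), `2` = wfCloud(80, tmpl, 5),
            `3` = wfCloud(80, tmpl, 5, shift = 2))
  u1 <- unitRecording("u", "DS", list(`1` = c(1, 2), `2` = c(1, 2),
                                      `3` = c(1, 2)), w)
  u2 <- unitRecording("u", "DS", list(`1` = c(1, 2), `2` = c(1, 2),
                                      `3` = c(1, 2)),
                      lapply(w, function(m) 7.3 * m))
  r1 <- assessStability(u1); r2 <- assessStability(u2)
  expect_identical(r1$table$pass, r2$table$pass)
  expect_identical(r1$overallStable, r2$overallStable)
})

test_that("stationary Gaussian units are usually stable at k = 1.96", {
  set.seed(44)
  tmpl <- 70 * sin(seq(0, 3 * pi, length.out = 20))
  ok <- vapply(1:20, function(i) {
    wf <- lapply(1:3, function(s) wfCloud(200, tmpl, 5))
    names(wf) <- 1:3
    u <- unitRecording("u", "M1",
                       setNames(rep(list(c(1, 2)), 3), 1:3), wf)
    assessStability(u)$overallStable
  }, TRUE)
  expect_gt(mean(ok), 0.9)
})

test_that("non-contiguous sessions are evaluated with a flag", {
  set.seed(45)
  tmpl <- 50 * sin(seq(0, 2 * pi, length.out = 12))
  u <- unitRecording("u", "M1",
                     list(`1` = c(1, 2), `3` = c(1, 2)),
                     list(`1` = wfCloud(60, tmpl, 3),
                          `3` = wfCloud(60, tmpl, 3)))
  expect_warning(res <- assessStability(u), "contiguous")
  expect_false(res$contiguous)
})
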