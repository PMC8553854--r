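test_that("k-means recovers perfectly separable alternating topographies", {
  set.seed(4)
  a <- rnorm(6); b <- rnorm(6)
  x <- cbind(a, b, a, b, a, b)
  cm <- kmeansTopographies(x, 2, nRestarts = 5, seed = 1)
  expect_equal(innerDistanceSum(cm), 0)
  lab <- clusterLabels(cm)
  expect_equal(lab[c(1, 3, 5)], rep(lab[1], 3))
  expect_equal(lab[c(2, 4, 6)], rep(lab[2], 3))
  expect_true(all(sort(unique(lab)) == 1:2))
  cen <- centroids(cm)
  expect_equal(sort(c(cosTheta(cen[, 1], a), cosTheta(cen[, 2], a))),
               sort(c(cosTheta(a, b), 1)), tolerance = 1e-12)
})

test_that("k = 1 returns the columnwise mean and the total variance", {
  set.seed(5)
  x <- matrix(rnorm(8 * 12), 8, 12)
  cm <- kmeansTopographies(x, 1, nRestarts = 2, seed = 1)
  expect_equal(centroids(cm)[, 1], rowMeans(x))
  expect_equal(innerDistanceSum(cm), sum(sweep(x, 1, rowMeans(x))^2))
})

test_that("k-means matches exhaustive partition search on small fixtures", {
  set.seed(6)
  for (rep in 1:3) {
    x <- matrix(rnorm(4 * 8), 4, 8)  # 8 timepoints
    ref <- bruteForceKmeans(x, 2)
    cm <- kmeansTopographies(x, 2, nRestarts = 50, maxIter = 100,
                             seed = rep)
    expect_equal(innerDistanceSum(cm), ref$withinss, tolerance = 1e-9)
  }
})

test_that("solutions are deterministic in the seed and robust across seeds", {
  m <- smallManifest(noiseSd = 2, nEpochs = 20, seed = 21L)
  dd <- simulateDataset(m)
  erps <- lapply(dd$epochSets, function(e) normalizeByGFP(averageEpochs(e)))
  gg <- grandGrandmean(erps)
  cm1 <- kmeansTopographies(gg, 3, nRestarts = 50, seed = 1)
  cm1b <- kmeansTopographies(gg, 3, nRestarts = 50, seed = 1)
  expect_identical(clusterLabels(cm1), clusterLabels(cm1b))
  expect_identical(innerDistanceSum(cm1), innerDistanceSum(cm1b))
  # 50 restarts: different seeds land on the same optimum
  cm2 <- kmeansTopographies(gg, 3, nRestarts = 50, seed = 99)
  expect_equal(innerDistanceSum(cm1), innerDistanceSum(cm2),
               tolerance = 1e-6)
  # and the hand-rolled Lloyd loop is cross-checked against stats::kmeans
  km <- stats::kmeans(t(erpData(gg)), centers = 3, nstart = 50,
                      iter.max = 100)
  expect_equal(innerDistanceSum(cm1), km$tot.withinss, tolerance = 1e-6)
})

test_that("k beyond the number of timepoints is refused", {
  x <- matrix(rnorm(12), 3, 4)
  expect_error(kmeansTopographies(x, 5, seed = 1), "exceeds")
})

test_that("noiseless synthetic data are recovered exactly at k = truth", {
  m <- smallManifest(noiseSd = 0, subjectSd = 0, nSubjects = 1, nEpochs = 1)
  dd <- simulateDataset(m)
  erp <- normalizeByGFP(averageEpochs(dd$epochSets[[1]]))
  cm <- kmeansTopographies(erp, 3, nRestarts = 20, seed = 3)
  seg <- segmentMicrostates(clusterLabels(cm), timesMs(erp))
  ms <- microstates(seg)
  expect_equal(ms$start_ms, c(0, 40, 80))
  expect_equal(ms$end_ms, c(40, 80, 120))
  # centroid-template alignment is exact
  tm <- templates(m@templateSet)
  ids <- m@timeline@segments$template_id
  for (i in seq_len(nrow(ms))) {
    ct <- cosTheta(centroids(cm)[, ms$cluster_id[i]], tm[, ids[i]])
    expect_equal(abs(ct), 1, tolerance = 1e-9)
  }
})

test_that("noisy recovery stays within one sample at high SNR", {
  # per-timepoint ERP SNR >= 10: envelope ~> 10 x noise sd of the mean
  m <- smallManifest(nChannels = 30, noiseSd = 1, subjectSd = 0,
                     nSubjects = 2, nEpochs = 40, seed = 8L)
  dd <- simulateDataset(m)
  erps <- lapply(dd$epochSets, function(e) normalizeByGFP(averageEpochs(e)))
  gg <- grandGrandmean(erps)
  cm <- kmeansTopographies(gg, 3, nRestarts = 50, seed = 2)
  seg <- segmentMicrostates(clusterLabels(cm), timesMs(gg))
  ms <- microstates(seg)
  expect_equal(nrow(ms), 3)
  expect_lte(max(abs(ms$start_ms - c(0, 40, 80))), 4)
  tm <- templates(m@templateSet)
  ids <- m@timeline@segments$template_id
  for (i in seq_len(nrow(ms))) {
    ct <- cosTheta(centroids(cm)[, ms$cluster_id[i]], tm[, ids[i]])
    expect_gte(abs(ct), 0.99)
  }
})

test_that("segmentation is a run-length encoding of the label sequence", {
  tms <- seq(0, 16, by = 4)
  seg <- segmentMicrostates(c(1, 1, 2, 2, 1), tms)
  ms <- microstates(seg)
  expect_equal(ms$cluster_id, c(1, 2, 1))
  expect_equal(ms$start_ms, c(0, 8, 16))
  expect_equal(ms$end_ms, c(8, 16, 20))
  # all labels equal: one microstate spanning the window
  one <- microstates(segmentMicrostates(rep(3, 5), tms))
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start_ms, one$end_ms), c(0, 20))
  # random sequences match an independent run-length encoder
  set.seed(7)
  for (rep in 1:5) {
    lab <- sample(1:3, 40, replace = TRUE)
    t40 <- seq(0, by = 4, length.out = 40)
    got <- microstates(segmentMicrostates(lab, t40))
    r <- rle(lab)
    expect_equal(got$cluster_id, r$values)
    expect_equal(got$end_ms - got$start_ms, 4 * r$lengths)
    # microstates cover the window and index in temporal order
    expect_equal(got$index, seq_len(nrow(got)))
    expect_equal(sum(got$end_ms - got$start_ms), 160)
  }
})

test_that("a duration floor merges short runs", {
  tms <- seq(0, by = 4, length.out = 10)
  lab <- c(1, 1, 1, 2, 1, 1, 1, 3, 3, 3)
  seg <- segmentMicrostates(lab, tms, minDurationMs = 8)
  expect_equal(microstates(seg)$cluster_id, c(1, 3))
})

test_that("microstate averaging equals brute-force columnwise means", {
  set.seed(8)
  tms <- seq(0, by = 4, length.out = 12)
  x <- matrix(rnorm(5 * 12), 5, 12)
  lab <- c(1, 1, 1, 2, 2, 3, 3, 3, 3, 1, 1, 2)
  seg <- segmentMicrostates(lab, tms)
  v <- applySegmentation(ERPMatrix(x, tms), seg)
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- c(1, head(ends, -1) + 1)
  for (i in seq_along(r$values)) {
    expect_equal(v[, i], rowMeans(x[, starts[i]:ends[i], drop = FALSE]),
                 ignore_attr = TRUE)
  }
  # single-timepoint microstate is that column; constant ERP gives
  # identical vectors
  xc <- matrix(rep(1:5, 12), 5, 12)
  vc <- applySegmentation(ERPMatrix(xc, tms), seg)
  expect_true(all(vc == 1:5))
  expect_error(applySegmentation(ERPMatrix(x, tms + 1), seg), "match")
})

test_that("the k sweep emits elbow data with non-increasing distances", {
  m <- smallManifest(noiseSd = 1, nEpochs = 10, seed = 31L)
  dd <- simulateDataset(m)
  erps <- lapply(dd$epochSets, function(e) normalizeByGFP(averageEpochs(e)))
  gg <- grandGrandmean(erps)
  sw <- sweepK(gg, kRange = 2:6, nRestarts = 25, seed = 1)
  expect_equal(sw$summary$k, 2:6)
  expect_true(all(diff(sw$summary$inner_distance_sum) <= 1e-9))
  # elbow at the generative truth: sharp drop until k = 3, flat after
  drop23 <- sw$summary$inner_distance_sum[1] -
    sw$summary$inner_distance_sum[2]
  drop34 <- sw$summary$inner_distance_sum[2] -
    sw$summary$inner_distance_sum[3]
  expect_gt(drop23, 10 * drop34)
  expect_equal(sw$kneeSuggestion, 3L)
  # durations table covers the window for every k
  for (k in 2:6) {
    d <- sw$durations[sw$durations$k == k, ]
    expect_equal(sum(d$duration_ms), 120)
  }
  # single-k sweep: single-row table
  sw1 <- sweepK(gg, kRange = 2, nRestarts = 5, seed = 1)
  expect_equal(nrow(sw1$summary), 1)
})
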