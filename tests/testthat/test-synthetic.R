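test_that("templates have unit GFP and the requested angular separation", {
  # single template: normalization forced
  one <- makeTemplates(1, 30, 60, seed = 5)
  expect_equal(computeGFP(templates(one)[, 1]), 1)
  # two orthogonal 2-channel vectors at 90 degrees
  ts2 <- makeTemplates(2, 2, 90, seed = 5)
  expect_equal(sum(templates(ts2)[, 1] * templates(ts2)[, 2]), 0)
  expect_equal(apply(templates(ts2), 2, computeGFP), c(T1 = 1, T2 = 1))
  # pairwise |cos| <= 0.5 verified by direct dot products (oracle)
  ts <- makeTemplates(3, 30, 60, seed = 1)
  tm <- templates(ts)
  for (i in 1:2) for (j in (i + 1):3) {
    ct <- sum(tm[, i] * tm[, j]) /
      (sqrt(sum(tm[, i]^2)) * sqrt(sum(tm[, j]^2)))
    expect_lte(abs(ct), 0.5 + 1e-12)
  }
  # determinism given the seed
  expect_identical(templates(makeTemplates(3, 30, 60, seed = 1)), tm)
  # infeasible request fails explicitly
  expect_error(makeTemplates(4, 2, 90, seed = 1), "orthogonal")
  expect_error(makeTemplates(50, 3, 80, seed = 1, maxTries = 50),
               "infeasible")
})

test_that("timelines are contiguous with distinct adjacent templates", {
  tl <- makeTimeline(c("T1", "T2", "T1"), c(40, 40, 40))
  seg <- tl@segments
  expect_equal(seg$start_ms, c(0, 40, 80))
  expect_equal(seg$end_ms, c(40, 80, 120))
  expect_error(makeTimeline(c("T1", "T1"), c(40, 40)), "distinct")
  # tiling covers the window exactly, remainder absorbed by a short segment
  tl2 <- tileTimeline(c("T1", "T2"), c(0, 600), 88)
  expect_equal(tl2@segments$end_ms[nrow(tl2@segments)], 600)
  expect_error(tileTimeline("T1", c(0, 600), 100), "single template")
})

test_that("simulated epochs follow envelope x template plus seeded noise", {
  ts <- makeTemplates(3, 8, 60, seed = 2)
  tl <- tileTimeline(ts, c(0, 120), 40)
  tms <- windowTimes(c(0, 120))
  env <- rep(10, length(tms))
  # noiseless: every column is exactly on its segment's template
  ep <- simulateEpoch(tl, ts, env, noiseSd = 0, seed = 1)
  segOfT <- rep(1:3, each = 10)
  for (t in seq_along(tms)) {
    tmpl <- templates(ts)[, tl@segments$template_id[segOfT[t]]]
    expect_equal(cosTheta(ep[, t], tmpl), 1)
    expect_equal(ep[, t], 10 * tmpl)
  }
  # null-signal limit: pure noise with per-channel sd ~ noiseSd
  epn <- simulateEpoch(tl, ts, env * 0, noiseSd = 2, seed = 3)
  expect_equal(sd(as.numeric(epn)), 2, tolerance = 0.1)
  # moderate SNR: mean cosine to the active template stays high
  # (oracle: Monte-Carlo estimate under sd 1 noise on an envelope of 10)
  eps <- simulateEpoch(tl, ts, env, noiseSd = 1, seed = 4)
  cts <- vapply(seq_along(tms), function(t) {
    cosTheta(eps[, t], templates(ts)[, tl@segments$template_id[segOfT[t]]])
  }, numeric(1))
  expect_gte(mean(cts), 0.95)
  # determinism and error on unknown template ids
  expect_identical(simulateEpoch(tl, ts, env, 1, seed = 4), eps)
  badTl <- makeTimeline(c("T1", "T9"), c(60, 60))
  expect_error(simulateEpoch(badTl, ts, env, 0, seed = 1), "T9")
  expect_error(simulateEpoch(tl, ts, env[-1], 0, seed = 1), "length")
})

test_that("datasets have the promised shape and are bit-reproducible", {
  m <- smallManifest(nSubjects = 2, nEpochs = 5)
  dd <- simulateDataset(m)
  expect_length(dd$epochSets, 4)  # 2 subjects x 2 conditions
  expect_setequal(names(dd$epochSets),
                  c("S01.A", "S01.B", "S02.A", "S02.B"))
  for (es in dd$epochSets) {
    expect_equal(dim(erpData(es)), c(5, 8, 30))
  }
  dd2 <- simulateDataset(m)
  expect_identical(lapply(dd$epochSets, erpData),
                   lapply(dd2$epochSets, erpData))
})

test_that("the injected effect angle is realized exactly in the noiseless means", {
  m <- smallManifest(nChannels = 30, angleDeg = 60, affected = 2L,
                     noiseSd = 0, subjectSd = 0)
  dd <- simulateDataset(m)
  a <- erpData(averageEpochs(dd$epochSets[["S01.A"]]))
  b <- erpData(averageEpochs(dd$epochSets[["S01.B"]]))
  tms <- windowTimes(c(0, 120))
  inSeg2 <- tms >= 40 & tms < 80
  for (t in which(inSeg2)) {
    ct <- cosTheta(a[, t], b[, t])
    expect_lt(abs(acos(ct) * 180 / pi - 60), 1e-6)
    expect_equal(ct, cos(60 * pi / 180))
  }
  # unaffected segments are identical across conditions
  expect_equal(a[, !inSeg2], b[, !inSeg2])
  # amplitude ratio scales the envelope of the affected segment only
  m2 <- smallManifest(nChannels = 30, angleDeg = 0, affected = 2L,
                      amplitudeRatio = 2, noiseSd = 0, subjectSd = 0)
  d2 <- simulateDataset(m2)
  gA <- gfpCurve(erpData(averageEpochs(d2$epochSets[["S01.A"]])))
  gB <- gfpCurve(erpData(averageEpochs(d2$epochSets[["S01.B"]])))
  expect_equal(gB[inSeg2], 2 * gA[inSeg2])
  expect_equal(gB[!inSeg2], gA[!inSeg2])
})

test_that("subject jitter perturbs templates but keeps them unit GFP", {
  m <- smallManifest(subjectSd = 0.2, noiseSd = 0, nSubjects = 3)
  dd <- simulateDataset(m)
  erp1 <- erpData(averageEpochs(dd$epochSets[["S01.A"]]))
  erp2 <- erpData(averageEpochs(dd$epochSets[["S02.A"]]))
  expect_gt(max(abs(erp1 - erp2)), 0)       # subjects differ
  expect_equal(gfpCurve(erp1), m@envelope)  # but GFP structure is intact
})

test_that("truth manifests round-trip through JSON", {
  m <- smallManifest(angleDeg = 45, affected = 2L, noiseSd = 3,
                     subjectSd = 0.1)
  path <- tempfile(fileext = ".json")
  writeTruthManifest(m, path)
  m2 <- readTruthManifest(path)
  expect_equal(templates(m2@templateSet), templates(m@templateSet))
  expect_equal(m2@timeline@segments, m@timeline@segments)
  expect_equal(m2@effectSpec@angleDeg, 45)
  expect_identical(lapply(simulateDataset(m2)$epochSets, erpData),
                   lapply(simulateDataset(m)$epochSets, erpData))
})
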