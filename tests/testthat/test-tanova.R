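test_that("the cosine statistic behaves as an angle measure", {
  expect_equal(cosTheta(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosTheta(c(1, 2, 3), -c(1, 2, 3)), -1)
  expect_equal(cosTheta(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(cosTheta(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosTheta(1:3, 1:4), "dimension")
  # bounds, symmetry, and scale invariance (sign of the product of scales)
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    ct <- cosTheta(a, b)
    expect_gte(ct, -1); expect_lte(ct, 1)
    expect_equal(ct, cosTheta(b, a))
    expect_equal(cosTheta(2.5 * a, 0.3 * b), ct)
    expect_equal(cosTheta(-2.5 * a, 0.3 * b), -ct)
    expect_equal(cosTheta(-a, -b), ct)
  }
})

test_that("alpha adjustment divides by the number of tests", {
  expect_equal(round(adjustAlpha(0.05, 18), 4), 0.0028)
  expect_equal(round(adjustAlpha(0.05, 30), 4), 0.0017)
  expect_equal(round(adjustAlpha(0.05, 41), 4), 0.0012)
  expect_equal(adjustAlpha(0.05, 1), 0.05)
  expect_error(adjustAlpha(0.05, 0), ">= 1")
})

test_that("permutation p-values follow the add-one lower-tail convention", {
  null <- seq(0.1, 0.9, length.out = 3000)
  # observed below all null values: p = 1/3001
  expect_equal(tanovaP(0.05, null), 1 / 3001)
  # observed above all null values: p = 1
  expect_equal(tanovaP(0.95, null), 1)
  # observed at the median of an odd-sized null: p ~ 0.5
  nullOdd <- seq(0, 1, length.out = 3001)
  expect_equal(tanovaP(0.5, nullOdd), (1 + 1501) / 3002)
  # ties count as "at or below"
  expect_equal(tanovaP(0.5, c(0.5, 0.5, 0.7)), 3 / 4)
  # plain-rank convention never returns zero
  expect_equal(tanovaP(0.05, null, convention = "rank"), 1 / 3000)
  expect_error(tanovaP(0.5, numeric(0)), "empty")
})

test_that("identical pools give observed cosine 1 at or above every null value", {
  m <- smallManifest(noiseSd = 2, nEpochs = 8)
  dd <- simulateDataset(m)
  poolA <- poolEpochs(Filter(function(e) e@condition == "A", dd$epochSets))
  erp <- normalizeByGFP(averageEpochs(dd$epochSets[[1]]))
  cm <- kmeansTopographies(erp, 3, nRestarts = 10, seed = 1)
  seg <- segmentMicrostates(clusterLabels(cm), timesMs(erp))
  obs <- observedCosines(poolA, poolA, seg)
  expect_equal(obs, rep(1, nrow(microstates(seg))))
  null <- permutationNull(poolA, poolA, seg, nPerm = 50, seed = 1)
  expect_true(all(null <= 1 + 1e-12))
  expect_equal(dim(null), c(50, nrow(microstates(seg))))
  for (i in seq_along(obs)) expect_true(all(null[, i] <= obs[i] + 1e-12))
})

test_that("the null has one row per permutation and is seed-reproducible", {
  m <- smallManifest(noiseSd = 3, nEpochs = 6)
  dd <- simulateDataset(m)
  pools <- lapply(c("A", "B"), function(cond) {
    poolEpochs(Filter(function(e) e@condition == cond, dd$epochSets))
  })
  erp <- normalizeByGFP(averageEpochs(dd$epochSets[[1]]))
  seg <- segmentMicrostates(
    clusterLabels(kmeansTopographies(erp, 3, nRestarts = 5, seed = 1)),
    timesMs(erp))
  n1 <- permutationNull(pools[[1]], pools[[2]], seg, nPerm = 40, seed = 5)
  n2 <- permutationNull(pools[[1]], pools[[2]], seg, nPerm = 40, seed = 5)
  expect_identical(n1, n2)
  n3 <- permutationNull(pools[[1]], pools[[2]], seg, nPerm = 40, seed = 6)
  expect_false(identical(n1, n3))
  expect_equal(nrow(n1), 40)
  expect_error(permutationNull(pools[[1]], pools[[2]], seg, nPerm = 0),
               ">= 1")
  # stratified shuffling preserves per-subject epoch counts and still
  # produces a valid null
  ns <- permutationNull(pools[[1]], pools[[2]], seg, nPerm = 20, seed = 5,
                        stratified = TRUE)
  expect_true(all(ns >= -1 - 1e-12 & ns <= 1 + 1e-12))
})

test_that("runTanova ties the pieces together consistently", {
  m <- smallManifest(noiseSd = 3, nEpochs = 10, angleDeg = 90,
                     affected = 2L, seed = 17L)
  dd <- simulateDataset(m)
  poolA <- poolEpochs(Filter(function(e) e@condition == "A", dd$epochSets))
  poolB <- poolEpochs(Filter(function(e) e@condition == "B", dd$epochSets))
  erps <- lapply(dd$epochSets, function(e) normalizeByGFP(averageEpochs(e)))
  gg <- grandGrandmean(erps)
  seg <- segmentMicrostates(
    clusterLabels(kmeansTopographies(gg, 3, nRestarts = 20, seed = 1)),
    timesMs(gg))
  tr <- runTanova(poolA, poolB, seg, nPerm = 199, seed = 3)
  tb <- resultTable(tr)
  expect_equal(nrow(tb), nrow(microstates(seg)))
  expect_equal(tr@alphaAdj, 0.05 / nrow(tb))
  expect_equal(tb$significant, tb$p_value < tr@alphaAdj)
  # observed cosines match a direct recomputation
  expect_equal(tb$cos_theta_obs, observedCosines(poolA, poolB, seg))
  # p-values match tanovaP applied to the stored null
  for (i in seq_len(nrow(tb))) {
    expect_equal(tb$p_value[i],
                 tanovaP(tb$cos_theta_obs[i], nullDistribution(tr)[, i]))
  }
})

test_that("a strong confined effect is detected in the right microstate", {
  m <- smallManifest(nChannels = 30, noiseSd = 2, nEpochs = 30,
                     angleDeg = 60, affected = 2L, seed = 23L)
  dd <- simulateDataset(m)
  poolA <- poolEpochs(Filter(function(e) e@condition == "A", dd$epochSets))
  poolB <- poolEpochs(Filter(function(e) e@condition == "B", dd$epochSets))
  # segment on the generative boundaries (noiseless truth)
  tms <- windowTimes(c(0, 120))
  labTruth <- rep(1:3, each = 10)
  seg <- segmentMicrostates(labTruth, tms)
  tr <- runTanova(poolA, poolB, seg, nPerm = 199, seed = 5)
  tb <- resultTable(tr)
  expect_true(tb$significant[2])
  # the affected microstate has the smallest cosine
  expect_equal(which.min(tb$cos_theta_obs), 2L)
  # unaffected microstates: cosine near 1, not significant
  expect_false(tb$significant[1])
  expect_false(tb$significant[3])
})

test_that("type-I error is calibrated at the nominal level under the null", {
  # 220 null replicates; per replicate, test microstate 1 at alpha = 0.05
  # with 199 permutations (attainable level exactly 10/200). The rejection
  # count must fall inside the central 95% binomial band around 0.05.
  nRep <- 220
  rejections <- 0L
  for (r in seq_len(nRep)) {
    m <- smallManifest(nChannels = 8, noiseSd = 3, nEpochs = 10,
                       nSubjects = 1, seed = 1000L + r)
    dd <- simulateDataset(m)
    poolA <- dd$epochSets[["S01.A"]]@data
    poolB <- dd$epochSets[["S01.B"]]@data
    tms <- windowTimes(c(0, 120))
    seg <- segmentMicrostates(rep(1:3, each = 10), tms)
    obs <- observedCosines(poolA, poolB, seg, timesMs = tms)
    null <- permutationNull(poolA, poolB, seg, nPerm = 199,
                            seed = 2000L + r, timesMs = tms)
    p <- tanovaP(obs[1], null[, 1])
    if (p <= 0.05) rejections <- rejections + 1L
  }
  band <- qbinom(c(0.025, 0.975), nRep, 0.05)
  expect_gte(rejections, band[1])
  expect_lte(rejections, band[2])
})
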