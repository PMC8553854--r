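# Small synthetic study fixtures used across the suite. Sizes are scaled
# down (few channels, short window) so individual tests stay fast while the
# generative structure matches the full-size defaults.

smallManifest <- function(nTemplates = 3, nChannels = 8, window = c(0, 120),
                          durationMs = 40, angleDeg = 0,
                          affected = integer(), amplitudeRatio = 1,
                          nSubjects = 2, nEpochs = 5, noiseSd = 0,
                          subjectSd = 0, seed = 11L, minAngleDeg = 60) {
  ts <- makeTemplates(nTemplates, nChannels, minAngleDeg, seed = seed)
  tl <- tileTimeline(ts, window, durationMs)
  truthManifest(ts, tl,
                effect = effectSpec(affected, angleDeg, amplitudeRatio),
                nSubjects = nSubjects, nEpochsPerCondition = nEpochs,
                noiseSd = noiseSd, subjectSd = subjectSd,
                window = window, seed = seed)
}

# brute-force best k-partition of the columns of x by within-cluster
# squared-distance sum (exhaustive over all label assignments)
bruteForceKmeans <- function(x, k) {
  n <- ncol(x)
  best <- list(withinss = Inf)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    if (length(unique(lab)) < k) next
    ss <- 0
    for (j in seq_len(k)) {
      cols <- x[, lab == j, drop = FALSE]
      cen <- rowMeans(cols)
      ss <- ss + sum(sweep(cols, 1, cen)^2)
    }
    if (ss < best$withinss - 1e-12) best <- list(withinss = ss, labels = lab)
  }
  best
}
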