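## Channel-wise post-hoc localization: paired t-tests per channel within each
## microstate that the TANOVA flagged as globally different.

#' Equalize the epoch counts of two conditions
#'
#' Randomly subsamples (without replacement, seeded) the condition with more
#' epochs down to the size of the smaller one; the smaller condition is
#' returned unchanged. Satisfies the equal-n requirement of the paired test.
#'
#' @param epochsA,epochsB epochs x channels x timepoints arrays (or
#'   [poolEpochs()] lists, whose `data` element is used).
#' @param seed integer seed.
#' @return list with arrays `A` and `B` of equal first dimension, and `n`,
#'   the common epoch count.
#' @export
equalizeEpochs <- function(epochsA, epochsB, seed = 1L) {
  a <- if (is.list(epochsA) && !is.null(epochsA$data)) epochsA$data
       else epochsA
  b <- if (is.list(epochsB) && !is.null(epochsB$data)) epochsB$data
       else epochsB
  nA <- dim(a)[1]; nB <- dim(b)[1]
  if (is.null(nA) || is.null(nB) || nA < 1 || nB < 1) {
    stop("both conditions must contain at least one epoch")
  }
  n <- min(nA, nB)
  set.seed(as.integer(seed))
  if (nA > n) a <- a[sort(sample.int(nA, n)), , , drop = FALSE]
  if (nB > n) b <- b[sort(sample.int(nB, n)), , , drop = FALSE]
  list(A = a, B = b, n = n)
}

#' Channel-wise paired t-tests within significant microstates
#'
#' For every TANOVA-significant microstate and every channel, each epoch is
#' averaged over the microstate's timepoints (but not across epochs), epochs
#' are paired by index across the two equal-sized conditions, and a two-sided
#' paired t-test is computed. The level is Bonferroni-adjusted over channels:
#' `alpha / nChannels` (0.05 / 30 = 0.0017). Pairing unrelated epochs by
#' index is statistically arbitrary but mirrors the pooled design the global
#' test uses; set `paired = FALSE` for a Welch two-sample test instead.
#'
#' Channels whose paired differences have zero variance are flagged
#' `degenerate` and reported with `direction = 0` and `p = 1` by convention.
#'
#' @param epochsA,epochsB equal-sized epochs x channels x timepoints arrays
#'   (see [equalizeEpochs()]).
#' @param seg a [Segmentation-class].
#' @param significantMicrostates integer microstate indices to test
#'   (typically the TANOVA-significant ones).
#' @param alpha nominal level (default 0.05).
#' @param montage channel labels (default `ch1..chN`).
#' @param paired logical, paired-by-index t-test (default TRUE).
#' @param seed the equalization seed, recorded in the result.
#' @return a [PosthocTable-class].
#' @export
channelTTests <- function(epochsA, epochsB, seg, significantMicrostates,
                          alpha = 0.05, montage = NULL, paired = TRUE,
                          seed = 1L) {
  stopifnot(length(dim(epochsA)) == 3, length(dim(epochsB)) == 3)
  if (paired && dim(epochsA)[1] != dim(epochsB)[1]) {
    stop("paired tests require equal epoch counts; run equalizeEpochs() first")
  }
  nCh <- dim(epochsA)[2]
  if (is.null(montage)) montage <- paste0("ch", seq_len(nCh))
  aAdj <- adjustAlpha(alpha, nCh)
  ms <- seg@microstates
  rows <- list()
  for (m in significantMicrostates) {
    inMs <- seg@timesMs >= ms$start_ms[ms$index == m] - 1e-9 &
            seg@timesMs < ms$end_ms[ms$index == m] - 1e-9
    # per-epoch mean over the microstate's timepoints: epochs x channels
    avgA <- apply(epochsA[, , inMs, drop = FALSE], c(1, 2), mean)
    avgB <- apply(epochsB[, , inMs, drop = FALSE], c(1, 2), mean)
    for (ch in seq_len(nCh)) {
      xa <- avgA[, ch]; xb <- avgB[, ch]
      if (paired) {
        d <- xa - xb
        degenerate <- stats::sd(d) < 1e-12
        if (degenerate) {
          tt <- list(statistic = if (abs(mean(d)) < 1e-12) 0 else NA_real_,
                     p.value = 1)
        } else {
          ht <- stats::t.test(xa, xb, paired = TRUE)
          tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
        }
      } else {
        degenerate <- stats::sd(xa) < 1e-12 && stats::sd(xb) < 1e-12
        if (degenerate) {
          tt <- list(statistic = if (abs(mean(xa) - mean(xb)) < 1e-12) 0
                                 else NA_real_, p.value = 1)
        } else {
          ht <- stats::t.test(xa, xb, paired = FALSE)
          tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        microstate = m,
        channel = montage[ch],
        t = tt$statistic,
        p_value = tt$p.value,
        direction = if (degenerate) 0 else sign(mean(xa) - mean(xb)),
        significant = !degenerate & tt$p.value < aAdj,
        degenerate = degenerate
      )
    }
  }
  tb <- if (length(rows)) do.call(rbind, rows) else
    data.frame(microstate = integer(), channel = character(),
               t = numeric(), p_value = numeric(), direction = numeric(),
               significant = logical(), degenerate = logical())
  new("PosthocTable", table = tb, alphaAdj = aAdj,
      seed = as.integer(seed),
      nEqualized = as.integer(min(dim(epochsA)[1], dim(epochsB)[1])))
}
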