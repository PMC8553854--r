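## Permutation TANOVA: a global test for topographic differences between two
## conditions, per microstate, using the cosine of the angle between the
## conditions' microstate topography vectors as the statistic.

#' Cosine of the angle between two channel-space vectors
#'
#' Inner product divided by the product of the Euclidean norms. Ranges from
#' -1 (opposed maps) through 0 (orthogonal) to +1 (identical shape); it is
#' blind to overall scaling (up to sign), so after GFP normalization it
#' compares activity distributions, not amplitudes.
#'
#' @param a,b numeric vectors of equal length, both nonzero.
#' @return numeric(1) in `[-1, 1]`.
#' @examples
#' cosTheta(c(1, 0), c(1, 1))  # 1/sqrt(2)
#' @export
cosTheta <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal dimension")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine is undefined for a zero vector")
  max(-1, min(1, sum(a * b) / (na * nb)))
}

#' Bonferroni-adjust a significance level over microstates or channels
#'
#' @param alpha nominal level (default 0.05).
#' @param m number of simultaneous tests (>= 1).
#' @return alpha / m. Summaries display it rounded to 4 decimals (0.05 / 18 =
#'   0.0028, 0.05 / 30 = 0.0017, 0.05 / 41 = 0.0012).
#' @export
adjustAlpha <- function(alpha = 0.05, m) {
  if (m < 1) stop("'m' must be >= 1")
  alpha / m
}

#' Permutation p-value for an observed cosine
#'
#' One-sided lower-tail test: small cos theta means the two condition maps
#' are more dissimilar than permuted splits, so the p-value is the
#' (add-one-corrected) fraction of null values at or below the observed one.
#' Ties count as "at or below" (conservative).
#'
#' @param cosThetaObs observed statistic.
#' @param null numeric vector of null statistics.
#' @param convention `"add-one"` (default): `p = (1 + #\{null <= obs\}) /
#'   (nPerm + 1)`, never exactly zero; `"rank"`: `max(1, #\{null <= obs\}) /
#'   nPerm`.
#' @return numeric(1) in (0, 1].
#' @export
tanovaP <- function(cosThetaObs, null, convention = c("add-one", "rank")) {
  convention <- match.arg(convention)
  if (!length(null)) stop("null distribution is empty")
  r <- sum(null <= cosThetaObs)
  switch(convention,
    "add-one" = (1 + r) / (length(null) + 1),
    "rank" = max(1L, r) / length(null)
  )
}

#' Pool the epochs of several EpochSets into one array
#'
#' Concatenates epochs along the first dimension after checking that montage
#' and time axis agree. Used to build the per-condition pools the permutation
#' scheme shuffles (epochs of all subjects pooled, ignoring subject nesting).
#'
#' @param epochSets list of [EpochSet-class] objects.
#' @return list with `data` (epochs x channels x timepoints array),
#'   `timesMs`, `montage`, and `subject` (factor, the source subject of each
#'   epoch, for optional stratified shuffling).
#' @export
poolEpochs <- function(epochSets) {
  stopifnot(length(epochSets) >= 1)
  ref <- epochSets[[1]]
  for (es in epochSets) {
    if (!identical(es@montage, ref@montage) ||
        max(abs(es@timesMs - ref@timesMs)) > 1e-9) {
      stop("epoch sets differ in montage or time axis; cannot pool")
    }
  }
  mats <- lapply(epochSets, function(es) es@data)
  nTot <- sum(vapply(mats, function(m) dim(m)[1], integer(1)))
  arr <- array(0, dim = c(nTot, dim(ref@data)[2], dim(ref@data)[3]))
  subj <- character(nTot)
  at <- 0L
  for (i in seq_along(mats)) {
    n <- dim(mats[[i]])[1]
    arr[at + seq_len(n), , ] <- mats[[i]]
    subj[at + seq_len(n)] <- epochSets[[i]]@subjectId
    at <- at + n
  }
  list(data = arr, timesMs = ref@timesMs, montage = ref@montage,
       subject = factor(subj))
}

# Timepoint index groups of a segmentation (one integer vector per
# microstate), on the segmentation's own sampling grid.
.microstateIndexGroups <- function(seg) {
  ms <- seg@microstates
  lapply(seq_len(nrow(ms)), function(i) {
    which(seg@timesMs >= ms$start_ms[i] - 1e-9 &
          seg@timesMs < ms$end_ms[i] - 1e-9)
  })
}

# GFP-normalize a channels x timepoints matrix and collapse it into one
# topography vector per microstate index group (fast path, no S4).
.msVectors <- function(mat, groups, tol = 1e-12) {
  mu <- colMeans(mat)
  centered <- sweep(mat, 2, mu)
  g <- sqrt(colMeans(centered^2))
  if (any(g <= tol)) {
    stop(sprintf("degenerate topography (GFP <= %g) at timepoint index %s",
                 tol, paste(utils::head(which(g <= tol), 5),
                            collapse = ", ")))
  }
  mn <- sweep(mat, 2, g, "/")
  vapply(groups, function(idx) rowMeans(mn[, idx, drop = FALSE]),
         numeric(nrow(mat)))
}

# Average an epochs x channels x timepoints array, GFP-normalize the average,
# and collapse it into per-microstate topography vectors.
.microstateVectorsFromEpochs <- function(arr, seg, montage, timesMs) {
  avg <- colMeans(arr, dims = 1)
  normAvg <- normalizeByGFP(avg)
  applySegmentation(ERPMatrix(normAvg, timesMs, montage, normalized = TRUE),
                    seg)
}

#' Observed per-microstate cosines between two conditions
#'
#' Averages each condition's pooled epochs, GFP-normalizes the averages,
#' collapses them into microstate vectors, and returns cos theta per
#' microstate pair.
#'
#' @param poolA,poolB pooled conditions as returned by [poolEpochs()] (or
#'   bare epochs x channels x timepoints arrays).
#' @param seg a [Segmentation-class].
#' @param timesMs,montage required when bare arrays are given.
#' @return numeric vector, one cosine per microstate.
#' @export
observedCosines <- function(poolA, poolB, seg, timesMs = NULL,
                            montage = NULL) {
  pa <- .asPool(poolA, timesMs, montage)
  pb <- .asPool(poolB, timesMs, montage)
  va <- .microstateVectorsFromEpochs(pa$data, seg, pa$montage, pa$timesMs)
  vb <- .microstateVectorsFromEpochs(pb$data, seg, pb$montage, pb$timesMs)
  vapply(seq_len(ncol(va)), function(i) cosTheta(va[, i], vb[, i]),
         numeric(1))
}

.asPool <- function(pool, timesMs = NULL, montage = NULL) {
  if (is.list(pool) && !is.null(pool$data)) return(pool)
  arr <- pool
  stopifnot(length(dim(arr)) == 3)
  list(data = arr,
       timesMs = timesMs %||% seq_len(dim(arr)[3]),
       montage = montage %||% paste0("ch", seq_len(dim(arr)[2])),
       subject = factor(rep("pooled", dim(arr)[1])))
}

#' Permutation null distributions of the per-microstate cosine
#'
#' Implements the epoch-shuffling scheme: conditions A and B are pooled; in
#' each permutation the pooled epochs are shuffled and the first `nA` are
#' relabeled condition A, the rest condition B; each pseudo-condition is
#' averaged across epochs, GFP-normalized, collapsed into microstate vectors,
#' and cos theta recorded per microstate. Subject nesting is ignored by
#' default (every epoch is exchangeable); `stratified = TRUE` instead
#' shuffles epochs within each subject, preserving each subject's epoch count
#' per pseudo-condition.
#'
#' @param poolA,poolB pooled conditions ([poolEpochs()] output or bare
#'   arrays).
#' @param seg a [Segmentation-class].
#' @param nPerm number of permutations (default 3000).
#' @param seed integer seed; the null is bit-reproducible.
#' @param stratified logical, shuffle within subjects (default FALSE).
#' @param timesMs,montage required when bare arrays are given.
#' @return numeric matrix, nPerm x microstates.
#' @export
permutationNull <- function(poolA, poolB, seg, nPerm = 3000, seed = 1L,
                            stratified = FALSE, timesMs = NULL,
                            montage = NULL) {
  if (nPerm < 1) stop("'nPerm' must be >= 1")
  pa <- .asPool(poolA, timesMs, montage)
  pb <- .asPool(poolB, timesMs, montage)
  nA <- dim(pa$data)[1]; nB <- dim(pb$data)[1]
  if (nA < 1 || nB < 1) stop("both condition pools must be nonempty")
  nCh <- dim(pa$data)[2]; nTp <- dim(pa$data)[3]
  nTot <- nA + nB
  # flatten epochs to rows for fast pooled averaging
  flat <- matrix(0, nTot, nCh * nTp)
  flat[seq_len(nA), ] <- matrix(pa$data, nA, nCh * nTp)
  flat[nA + seq_len(nB), ] <- matrix(pb$data, nB, nCh * nTp)
  subject <- factor(c(as.character(pa$subject), as.character(pb$subject)))
  condOfEpoch <- rep(1:2, c(nA, nB))
  groups <- .microstateIndexGroups(seg)
  nMs <- nrow(seg@microstates)
  out <- matrix(NA_real_, nPerm, nMs)
  set.seed(as.integer(seed))
  for (p in seq_len(nPerm)) {
    if (stratified) {
      perm <- seq_len(nTot)
      for (lv in levels(subject)) {
        idx <- which(subject == lv)
        perm[idx] <- idx[sample.int(length(idx))]
      }
      # within-subject shuffle of condition labels: pseudo-A keeps each
      # subject's A-count
      pseudoA <- perm[condOfEpoch == 1L]
    } else {
      pseudoA <- sample.int(nTot, nA)
    }
    isA <- logical(nTot); isA[pseudoA] <- TRUE
    mA <- matrix(colMeans(flat[isA, , drop = FALSE]), nCh, nTp)
    mB <- matrix(colMeans(flat[!isA, , drop = FALSE]), nCh, nTp)
    vA <- .msVectors(mA, groups)
    vB <- .msVectors(mB, groups)
    out[p, ] <- vapply(seq_len(nMs),
                       function(i) cosTheta(vA[, i], vB[, i]), numeric(1))
  }
  colnames(out) <- paste0("MS", seg@microstates$index)
  out
}

#' Run the full TANOVA for one condition comparison
#'
#' Computes the observed per-microstate cosines, the permutation null, rank
#' p-values, and the Bonferroni-adjusted level alpha / m where `m` is the
#' number of microstates.
#'
#' @param poolA,poolB pooled conditions ([poolEpochs()] output or bare
#'   arrays).
#' @param seg a [Segmentation-class].
#' @param nPerm permutations (default 3000).
#' @param alpha nominal level (default 0.05).
#' @param seed integer seed.
#' @param stratified shuffle within subjects (default FALSE).
#' @param convention p-value convention, see [tanovaP()].
#' @param comparison character(2) condition labels, for reporting.
#' @param timesMs,montage required when bare arrays are given.
#' @return a [TanovaResult-class].
#' @export
runTanova <- function(poolA, poolB, seg, nPerm = 3000, alpha = 0.05,
                      seed = 1L, stratified = FALSE,
                      convention = c("add-one", "rank"),
                      comparison = c("A", "B"), timesMs = NULL,
                      montage = NULL) {
  convention <- match.arg(convention)
  obs <- observedCosines(poolA, poolB, seg, timesMs, montage)
  null <- permutationNull(poolA, poolB, seg, nPerm = nPerm, seed = seed,
                          stratified = stratified, timesMs = timesMs,
                          montage = montage)
  p <- vapply(seq_along(obs),
              function(i) tanovaP(obs[i], null[, i], convention),
              numeric(1))
  aAdj <- adjustAlpha(alpha, length(obs))
  tb <- data.frame(
    microstate = seg@microstates$index,
    cos_theta_obs = obs,
    p_value = p,
    significant = p < aAdj
  )
  new("TanovaResult", table = tb, null = null, alphaAdj = aAdj,
      nPerm = as.integer(nPerm), seed = as.integer(seed),
      comparison = as.character(comparison))
}
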