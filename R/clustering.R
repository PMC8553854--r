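## Polarity-sensitive k-means over timepoint topographies and temporal
## segmentation of the label sequence into microstates.

# Squared Euclidean distances from each column of x (channels x n) to each
# column of centers (channels x k): n x k matrix.
.sqDistToCenters <- function(x, centers) {
  xs <- colSums(x^2)
  cs <- colSums(centers^2)
  d2 <- outer(xs, cs, "+") - 2 * crossprod(x, centers)
  pmax(d2, 0)
}

# One Lloyd run from given initial centroid columns. Assignment ties break to
# the lowest cluster id (max.col with ties.method = "first" on negated
# distances). Returns NULL if a cluster empties.
.lloydRun <- function(x, centers, maxIter) {
  labels <- integer(ncol(x))
  for (iter in seq_len(maxIter)) {
    d2 <- .sqDistToCenters(x, centers)
    newLabels <- max.col(-d2, ties.method = "first")
    if (length(unique(newLabels)) < ncol(centers)) return(NULL)
    if (identical(newLabels, labels)) break
    labels <- newLabels
    for (j in seq_len(ncol(centers))) {
      centers[, j] <- rowMeans(x[, labels == j, drop = FALSE])
    }
  }
  d2 <- .sqDistToCenters(x, centers)
  list(labels = labels, centers = centers,
       withinss = sum(d2[cbind(seq_len(ncol(x)), labels)]))
}

#' k-means clustering of ERP timepoint topographies
#'
#' Clusters the columns (timepoint topographies) of an ERP matrix with
#' standard Lloyd iterations and squared Euclidean distance. The distance is
#' polarity-sensitive: a map and its polarity reversal fall in different
#' clusters, because phase-locked ERP topographies carry signed amplitude
#' information. Each restart initializes the centroids as `k` distinct
#' timepoint topographies sampled without replacement (seeded); the
#' best-of-restarts solution by within-cluster sum of squared distances is
#' returned. A restart whose iteration empties a cluster is re-seeded and
#' counted.
#'
#' @param erp an [ERPMatrix-class] (typically the GFP-normalized
#'   grand-grandmean) or a channels x timepoints matrix.
#' @param k number of clusters (<= number of timepoints).
#' @param nRestarts independent seeded restarts (default 50).
#' @param maxIter Lloyd iteration cap per restart (default 100).
#' @param seed integer seed; the solution is deterministic given the seed.
#' @return a [ClusterModel-class].
#' @export
kmeansTopographies <- function(erp, k, nRestarts = 50, maxIter = 100,
                               seed = 1L) {
  x <- if (is(erp, "ERPMatrix")) erp@data else as.matrix(erp)
  nTp <- ncol(x)
  if (k > nTp) stop(sprintf("k (%d) exceeds the number of timepoints (%d)",
                            k, nTp))
  stopifnot(k >= 1, nRestarts >= 1, maxIter >= 1)
  best <- NULL
  nReseeds <- 0L
  for (r in seq_len(nRestarts)) {
    attempt <- 0L
    repeat {
      set.seed(.deriveSeed(seed, r, attempt))
      init <- x[, sample.int(nTp, k), drop = FALSE]
      # distinct topographies: degenerate duplicated columns would empty a
      # cluster immediately; treat that as an empty-cluster reseed too
      run <- .lloydRun(x, init, maxIter)
      if (!is.null(run)) break
      attempt <- attempt + 1L
      nReseeds <- nReseeds + 1L
      if (attempt > 100L) {
        stop("could not find a restart without empty clusters; k may be too large for the data")
      }
    }
    if (is.null(best) || run$withinss < best$withinss) best <- run
  }
  new("ClusterModel", k = as.integer(k), centroids = best$centers,
      labels = as.integer(best$labels),
      innerDistanceSum = best$withinss, nRestarts = as.integer(nRestarts),
      maxIter = as.integer(maxIter), seed = as.integer(seed),
      nReseeds = nReseeds)
}

#' Segment a cluster-label sequence into microstates
#'
#' Maximal runs of consecutive timepoints with the same cluster label become
#' microstates, numbered in temporal order. Several microstates may share a
#' cluster id (clusters recur over time). Optionally, runs shorter than a
#' duration floor are absorbed into the preceding run (or the following one
#' at the window start).
#'
#' @param labels integer cluster ids, one per timepoint.
#' @param timesMs matching time axis (constant step).
#' @param minDurationMs if > 0, runs shorter than this floor are merged into
#'   the preceding run (default 0: no floor, so microstates shorter than the
#'   usual 60-120 ms convention are kept).
#' @return a [Segmentation-class]. Microstate intervals are half-open:
#'   `end_ms` of run ending at sample i is the start of sample i + 1.
#' @export
segmentMicrostates <- function(labels, timesMs, minDurationMs = 0) {
  stopifnot(length(labels) == length(timesMs), length(labels) >= 1)
  dt <- if (length(timesMs) > 1) timesMs[2] - timesMs[1] else 1
  r <- rle(as.integer(labels))
  if (minDurationMs > 0 && length(r$lengths) > 1) {
    repeat {
      short <- which(r$lengths * dt < minDurationMs)
      if (!length(short)) break
      i <- short[1]
      j <- if (i == 1) 2L else i - 1L
      r$lengths[j] <- r$lengths[j] + r$lengths[i]
      r$lengths <- r$lengths[-i]
      r$values <- r$values[-i]
      # re-merge identical neighbours created by the absorption
      r <- rle(inverse.rle(r))
    }
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ms <- data.frame(
    index = seq_along(r$values),
    start_ms = timesMs[starts],
    end_ms = timesMs[ends] + dt,
    cluster_id = r$values
  )
  window <- c(timesMs[1], timesMs[length(timesMs)] + dt)
  new("Segmentation", microstates = ms, window = window, timesMs = timesMs)
}

#' Average an ERP within each microstate
#'
#' Returns one topography per microstate: the mean over the microstate's
#' timepoints of the ERP columns.
#'
#' @param erp an [ERPMatrix-class] or channels x timepoints matrix whose time
#'   axis matches the segmentation's.
#' @param seg a [Segmentation-class].
#' @return numeric matrix, channels x microstates (columns named `MS1..MSM`).
#' @export
applySegmentation <- function(erp, seg) {
  x <- if (is(erp, "ERPMatrix")) erp@data else as.matrix(erp)
  tms <- if (is(erp, "ERPMatrix")) erp@timesMs else seg@timesMs
  if (length(tms) != length(seg@timesMs) ||
      max(abs(tms - seg@timesMs)) > 1e-9) {
    stop("ERP time axis does not match the segmentation window")
  }
  ms <- seg@microstates
  out <- matrix(0, nrow(x), nrow(ms))
  for (i in seq_len(nrow(ms))) {
    inMs <- seg@timesMs >= ms$start_ms[i] - 1e-9 &
            seg@timesMs < ms$end_ms[i] - 1e-9
    out[, i] <- rowMeans(x[, inMs, drop = FALSE])
  }
  rownames(out) <- if (is(erp, "ERPMatrix")) erp@montage else rownames(x)
  colnames(out) <- paste0("MS", ms$index)
  out
}

#' Sweep k and collect model-size diagnostics
#'
#' Fits [kmeansTopographies()] for every k in `kRange` and tabulates the
#' within-cluster distance sum (elbow-plot data) and the microstate durations
#' of the induced segmentation (stacked-duration data). Model choice is
#' deliberately not automated: inspect the elbow and duration tables and set
#' k in the configuration. A knee heuristic (maximum second difference of the
#' distance curve) is reported as a suggestion only.
#'
#' @param erp an [ERPMatrix-class] or matrix.
#' @param kRange integer vector of k values (default 2:20).
#' @param nRestarts,maxIter,seed passed to [kmeansTopographies()].
#' @param keepModels logical, retain the fitted [ClusterModel-class] objects
#'   (default FALSE).
#' @return list with `summary` (data.frame: k, inner_distance_sum,
#'   n_microstates), `durations` (data.frame: k, microstate, start_ms,
#'   end_ms, cluster_id, duration_ms), `kneeSuggestion` (integer or NA), and
#'   optionally `models`.
#' @export
sweepK <- function(erp, kRange = 2:20, nRestarts = 50, maxIter = 100,
                   seed = 1L, keepModels = FALSE) {
  stopifnot(length(kRange) >= 1, all(kRange >= 1))
  tms <- if (is(erp, "ERPMatrix")) erp@timesMs else
    seq_len(ncol(as.matrix(erp)))
  rows <- vector("list", length(kRange))
  durs <- vector("list", length(kRange))
  models <- if (keepModels) vector("list", length(kRange)) else NULL
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    cm <- kmeansTopographies(erp, k, nRestarts, maxIter,
                             seed = .deriveSeed(seed, k))
    seg <- segmentMicrostates(cm@labels, tms)
    ms <- seg@microstates
    rows[[i]] <- data.frame(k = k,
                            inner_distance_sum = cm@innerDistanceSum,
                            n_microstates = nrow(ms))
    durs[[i]] <- cbind(k = k, ms,
                       duration_ms = ms$end_ms - ms$start_ms)
    if (keepModels) models[[i]] <- cm
  }
  summary <- do.call(rbind, rows)
  knee <- NA_integer_
  if (nrow(summary) >= 3) {
    d2 <- diff(summary$inner_distance_sum, differences = 2)
    knee <- summary$k[which.max(d2) + 1L]
  }
  out <- list(summary = summary, durations = do.call(rbind, durs),
              kneeSuggestion = knee)
  if (keepModels) out$models <- models
  out
}
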