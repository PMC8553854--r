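#' Global field power of a topography
#'
#' GFP is the spatial standard deviation of the scalp potential at one
#' timepoint: the root mean square of the deviations from the spatial mean,
#' using the population (n, not n - 1) form.
#'
#' @param topography numeric vector of channel values (length >= 2).
#' @return numeric(1), the GFP.
#' @examples
#' computeGFP(c(1, -1))          # 1
#' computeGFP(c(3, 1, -1, -3))   # sqrt(5)
#' @export
computeGFP <- function(topography) {
  if (length(topography) < 2) {
    stop("GFP requires at least 2 channels")
  }
  sqrt(mean((topography - mean(topography))^2))
}

#' GFP at every timepoint of a channels x timepoints matrix
#'
#' @param mat numeric matrix, channels x timepoints.
#' @return numeric vector of per-timepoint GFP values.
#' @export
gfpCurve <- function(mat) {
  if (nrow(mat) < 2) stop("GFP requires at least 2 channels")
  mu <- colMeans(mat)
  sqrt(colMeans(sweep(mat, 2, mu)^2))
}

#' Construct an ERPMatrix
#'
#' @param data numeric matrix, channels x timepoints.
#' @param timesMs numeric time axis (ms).
#' @param montage character channel labels; defaults to the matrix rownames
#'   or generic `ch1..chN` labels.
#' @param normalized logical(1), whether every column has unit GFP.
#' @param provenance character(1) free-text origin tag.
#' @return an [ERPMatrix-class].
#' @export
ERPMatrix <- function(data, timesMs, montage = NULL, normalized = FALSE,
                      provenance = "unspecified") {
  data <- as.matrix(data)
  if (is.null(montage)) {
    montage <- if (!is.null(rownames(data))) rownames(data)
               else paste0("ch", seq_len(nrow(data)))
  }
  rownames(data) <- montage
  new("ERPMatrix", data = data, timesMs = as.numeric(timesMs),
      montage = montage, normalized = isTRUE(normalized),
      provenance = provenance)
}

#' Baseline-correct an epoch or ERP matrix
#'
#' Subtracts, per channel, the mean over the baseline window from every
#' timepoint. The baseline window is a closed interval `[t0, t1]` on the time
#' axis and must contain at least one sample.
#'
#' @param epoch numeric matrix, channels x timepoints.
#' @param timesMs numeric time axis matching the columns.
#' @param baselineWindow numeric(2), `(t0_ms, t1_ms)` of the baseline period.
#' @return the corrected matrix (same shape).
#' @export
baselineCorrect <- function(epoch, timesMs, baselineWindow) {
  epoch <- as.matrix(epoch)
  stopifnot(ncol(epoch) == length(timesMs), length(baselineWindow) == 2)
  inWin <- timesMs >= baselineWindow[1] & timesMs <= baselineWindow[2]
  if (!any(inWin)) {
    stop("baseline window contains no samples of the time axis")
  }
  base <- rowMeans(epoch[, inWin, drop = FALSE])
  epoch - base
}

#' Average the epochs of an EpochSet into an ERP
#'
#' Elementwise mean over the epoch dimension. The result is not normalized.
#'
#' @param epochs an [EpochSet-class] (or a 3-way epochs x channels x
#'   timepoints array).
#' @param timesMs,montage time axis and channel labels, required only when
#'   `epochs` is a bare array.
#' @return an [ERPMatrix-class] with `normalized = FALSE`.
#' @export
averageEpochs <- function(epochs, timesMs = NULL, montage = NULL) {
  if (is(epochs, "EpochSet")) {
    arr <- epochs@data
    timesMs <- epochs@timesMs
    montage <- epochs@montage
    prov <- paste(epochs@subjectId, epochs@condition, sep = "/")
  } else {
    arr <- epochs
    prov <- "array"
    if (is.null(timesMs)) timesMs <- seq_len(dim(arr)[3])
    if (is.null(montage)) montage <- paste0("ch", seq_len(dim(arr)[2]))
  }
  if (length(dim(arr)) != 3 || dim(arr)[1] < 1) {
    stop("need at least one epoch in a 3-way array")
  }
  avg <- colMeans(arr, dims = 1)  # channels x timepoints
  ERPMatrix(avg, timesMs, montage, normalized = FALSE, provenance = prov)
}

#' Normalize an ERP by its per-timepoint GFP
#'
#' Divides all channel values at each timepoint by that timepoint's GFP, so
#' the result has unit spatial standard deviation everywhere. Differences
#' between normalized ERPs then reflect changes in the distribution of
#' activity, not overall amplitude. Idempotent.
#'
#' @param erp an [ERPMatrix-class] (or a channels x timepoints matrix).
#' @param tol GFP values at or below this are treated as degenerate
#'   topographies and raise an error naming the timepoint (default 1e-12).
#' @return an [ERPMatrix-class] with `normalized = TRUE` (or a matrix when a
#'   matrix was supplied).
#' @export
normalizeByGFP <- function(erp, tol = 1e-12) {
  mat <- if (is(erp, "ERPMatrix")) erp@data else as.matrix(erp)
  gfp <- gfpCurve(mat)
  bad <- which(gfp <= tol)
  if (length(bad)) {
    stop(sprintf(
      "degenerate topography (GFP <= %g) at timepoint index %s",
      tol, paste(utils::head(bad, 5), collapse = ", ")))
  }
  out <- sweep(mat, 2, gfp, "/")
  if (is(erp, "ERPMatrix")) {
    ERPMatrix(out, erp@timesMs, erp@montage, normalized = TRUE,
              provenance = erp@provenance)
  } else {
    out
  }
}

#' Grand-grandmean of normalized subject ERPs
#'
#' Elementwise mean across a list of GFP-normalized, shape-compatible ERPs
#' (typically one per subject and condition, pooled over all conditions).
#' By default the average is *not* re-normalized afterwards; set
#' `renormalize = TRUE` to divide the result by its own GFP again before
#' clustering.
#'
#' @param erps list of normalized [ERPMatrix-class] objects.
#' @param renormalize logical(1), re-normalize the average (default FALSE).
#' @return an [ERPMatrix-class] with provenance `"grand-grandmean"`.
#' @export
grandGrandmean <- function(erps, renormalize = FALSE) {
  stopifnot(length(erps) >= 1)
  norm <- vapply(erps, isNormalized, logical(1))
  if (!all(norm)) {
    stop("all input ERPs must be GFP-normalized (mixed normalization flags)")
  }
  d1 <- dim(erps[[1]]@data)
  ok <- vapply(erps, function(e) identical(dim(e@data), d1), logical(1))
  if (!all(ok)) stop("all input ERPs must have identical dimensions")
  acc <- Reduce(`+`, lapply(erps, function(e) e@data)) / length(erps)
  out <- ERPMatrix(acc, erps[[1]]@timesMs, erps[[1]]@montage,
                   normalized = FALSE, provenance = "grand-grandmean")
  if (renormalize) normalizeByGFP(out) else out
}
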