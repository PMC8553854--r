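#' @import methods
NULL

.tolGFP <- 1e-9

#' TemplateSet: generative microstate topographies
#'
#' A set of channel-space template topographies, each scaled to unit global
#' field power (GFP), together with template labels. Templates
#' are the generative counterpart of a microstate map: a momentary distribution
#' of activity across the scalp that the synthetic generator holds quasi-stable
#' over a segment of time.
#'
#' @slot templates numeric matrix, channels x templates; each column has
#'   GFP = 1 (within 1e-9).
#' @slot labels character vector of template identifiers (column names).
#' @slot minAngleDeg numeric(1), the minimum pairwise angular separation (in
#'   degrees) the set was built to satisfy.
#'
#' @seealso [makeTemplates()]
#' @export
setClass("TemplateSet",
  representation(
    templates = "matrix",
    labels = "character",
    minAngleDeg = "numeric"
  )
)

setValidity("TemplateSet", function(object) {
  tm <- object@templates
  msg <- character()
  if (!is.numeric(tm) || anyNA(tm)) {
    msg <- c(msg, "'templates' must be a numeric matrix without NAs")
  }
  if (length(object@labels) != ncol(tm)) {
    msg <- c(msg, "'labels' length must equal the number of template columns")
  }
  if (nrow(tm) >= 2) {
    gfp <- apply(tm, 2, computeGFP)
    if (any(abs(gfp - 1) > .tolGFP)) {
      msg <- c(msg, "every template must have unit GFP (within 1e-9)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Timeline: piecewise-stationary microstate schedule
#'
#' An ordered set of contiguous, non-overlapping segments that exactly cover
#' an analysis window, each segment carrying the id of the template active in
#' it. Adjacent segments must use distinct templates (otherwise they would be
#' one segment).
#'
#' @slot segments data.frame with columns `start_ms`, `end_ms`, `template_id`.
#'   Segments are half-open intervals `[start_ms, end_ms)` on the sampling
#'   grid.
#' @slot window numeric(2), `(t0_ms, t1_ms)` half-open analysis window.
#'
#' @seealso [makeTimeline()], [tileTimeline()]
#' @export
setClass("Timeline",
  representation(
    segments = "data.frame",
    window = "numeric"
  )
)

setValidity("Timeline", function(object) {
  seg <- object@segments
  msg <- character()
  need <- c("start_ms", "end_ms", "template_id")
  if (!all(need %in% names(seg))) {
    return("'segments' must have columns start_ms, end_ms, template_id")
  }
  if (length(object@window) != 2 || object@window[1] >= object@window[2]) {
    msg <- c(msg, "'window' must be (t0, t1) with t0 < t1")
  }
  if (nrow(seg) == 0) {
    msg <- c(msg, "timeline must contain at least one segment")
  } else {
    if (any(seg$end_ms <= seg$start_ms)) {
      msg <- c(msg, "every segment must have positive duration")
    }
    if (abs(seg$start_ms[1] - object@window[1]) > 1e-9 ||
        abs(seg$end_ms[nrow(seg)] - object@window[2]) > 1e-9) {
      msg <- c(msg, "segments must cover the window exactly")
    }
    if (nrow(seg) > 1) {
      if (any(abs(seg$start_ms[-1] - seg$end_ms[-nrow(seg)]) > 1e-9)) {
        msg <- c(msg, "segments must be contiguous and non-overlapping")
      }
      if (any(seg$template_id[-1] == seg$template_id[-nrow(seg)])) {
        msg <- c(msg, "adjacent segments must have distinct template ids")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' EffectSpec: controlled between-condition topographic perturbation
#'
#' Describes how condition B differs from condition A in a synthetic dataset:
#' in the affected segments the active template is rotated by `angleDeg`
#' within a seeded plane (so the cosine between the A and B topographies is
#' exactly `cos(angleDeg)`), and the GFP envelope may be scaled.
#'
#' @slot affectedSegments integer indices into the timeline's segments.
#' @slot angleDeg numeric(1) in `[0, 180]`, the angular perturbation.
#' @slot amplitudeRatio numeric(1) > 0, envelope scaling for condition B in
#'   the affected segments (1 = no amplitude effect).
#'
#' @export
setClass("EffectSpec",
  representation(
    affectedSegments = "integer",
    angleDeg = "numeric",
    amplitudeRatio = "numeric"
  ),
  prototype(
    affectedSegments = integer(),
    angleDeg = 0,
    amplitudeRatio = 1
  )
)

setValidity("EffectSpec", function(object) {
  msg <- character()
  if (length(object@angleDeg) != 1 || object@angleDeg < 0 ||
      object@angleDeg > 180) {
    msg <- c(msg, "'angleDeg' must be a single value in [0, 180]")
  }
  if (length(object@amplitudeRatio) != 1 || object@amplitudeRatio <= 0) {
    msg <- c(msg, "'amplitudeRatio' must be a single positive value")
  }
  if (length(msg)) msg else TRUE
})

#' TruthManifest: full specification of a synthetic dataset
#'
#' Ground truth for a simulated multi-subject, two-condition epoch study.
#' Together with the seed, a manifest fully determines the dataset, so any
#' downstream result can be checked against the generative truth.
#'
#' @slot templateSet a [TemplateSet-class].
#' @slot timeline a [Timeline-class].
#' @slot effectSpec an [EffectSpec-class]; condition B departs from A as
#'   specified here.
#' @slot nSubjects integer(1) >= 1.
#' @slot nEpochsPerCondition integer(1) >= 1.
#' @slot noiseSd numeric(1) >= 0, additive Gaussian noise sd per channel and
#'   timepoint, in microvolts.
#' @slot subjectSd numeric(1) >= 0, sd of per-subject additive template
#'   jitter (unitless, on the unit-GFP template scale).
#' @slot envelope numeric vector, the GFP waveform (microvolts) at each
#'   timepoint of the window.
#' @slot samplingRate numeric(1), Hz.
#' @slot seed integer(1), master seed.
#'
#' @seealso [truthManifest()], [simulateDataset()]
#' @export
setClass("TruthManifest",
  representation(
    templateSet = "TemplateSet",
    timeline = "Timeline",
    effectSpec = "EffectSpec",
    nSubjects = "integer",
    nEpochsPerCondition = "integer",
    noiseSd = "numeric",
    subjectSd = "numeric",
    envelope = "numeric",
    samplingRate = "numeric",
    seed = "integer"
  )
)

setValidity("TruthManifest", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "'nSubjects' must be >= 1")
  if (object@nEpochsPerCondition < 1L) {
    msg <- c(msg, "'nEpochsPerCondition' must be >= 1")
  }
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (object@subjectSd < 0) msg <- c(msg, "'subjectSd' must be >= 0")
  ntp <- windowSamples(object@timeline@window, object@samplingRate)
  if (length(object@envelope) != ntp) {
    msg <- c(msg, sprintf(
      "'envelope' length (%d) must match the %d timepoints implied by the window and sampling rate",
      length(object@envelope), ntp))
  }
  aff <- object@effectSpec@affectedSegments
  if (length(aff) &&
      (max(aff) > nrow(object@timeline@segments) || min(aff) < 1L)) {
    msg <- c(msg, "'affectedSegments' out of range for the timeline")
  }
  if (length(msg)) msg else TRUE
})

#' EpochSet: epoched multichannel EEG for one subject and condition
#'
#' @slot subjectId character(1).
#' @slot condition character(1) condition label.
#' @slot data numeric array, epochs x channels x timepoints, in microvolts.
#' @slot timesMs numeric vector of timepoint latencies (ms), strictly
#'   increasing with constant step.
#' @slot montage character vector of channel labels.
#' @slot samplingRate numeric(1), Hz.
#'
#' @export
setClass("EpochSet",
  representation(
    subjectId = "character",
    condition = "character",
    data = "array",
    timesMs = "numeric",
    montage = "character",
    samplingRate = "numeric"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- object@data
  if (length(dim(d)) != 3) {
    return("'data' must be a 3-way array (epochs x channels x timepoints)")
  }
  if (anyNA(d)) msg <- c(msg, "'data' must not contain missing values")
  if (length(object@montage) != dim(d)[2]) {
    msg <- c(msg, "montage length must equal the channel dimension")
  }
  if (length(object@timesMs) != dim(d)[3]) {
    msg <- c(msg, "time axis length must equal the timepoint dimension")
  }
  if (length(object@timesMs) > 1) {
    steps <- diff(object@timesMs)
    if (any(steps <= 0) || max(abs(steps - steps[1])) > 1e-9) {
      msg <- c(msg,
        "time axis must be strictly increasing with constant step")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ERPMatrix: channels x timepoints average
#'
#' The event-related potential for one subject and condition (or a grand
#' average), optionally GFP-normalized so that the spatial standard deviation
#' at every timepoint is 1.
#'
#' @slot data numeric matrix, channels x timepoints; microvolts, or unitless
#'   when normalized.
#' @slot timesMs numeric time axis (ms).
#' @slot montage character channel labels.
#' @slot normalized logical(1); if TRUE, GFP at every timepoint is 1
#'   (within 1e-9).
#' @slot provenance character(1), e.g. "S01/condA" or "grand-grandmean".
#'
#' @export
setClass("ERPMatrix",
  representation(
    data = "matrix",
    timesMs = "numeric",
    montage = "character",
    normalized = "logical",
    provenance = "character"
  )
)

setValidity("ERPMatrix", function(object) {
  msg <- character()
  if (anyNA(object@data)) msg <- c(msg, "'data' must not contain NAs")
  if (length(object@montage) != nrow(object@data)) {
    msg <- c(msg, "montage length must equal the number of rows")
  }
  if (length(object@timesMs) != ncol(object@data)) {
    msg <- c(msg, "time axis length must equal the number of columns")
  }
  if (isTRUE(object@normalized) && nrow(object@data) >= 2 &&
      ncol(object@data) > 0) {
    gfp <- apply(object@data, 2, computeGFP)
    if (any(abs(gfp - 1) > .tolGFP)) {
      msg <- c(msg, "normalized ERP must have unit GFP at every timepoint")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ClusterModel: k-means solution over timepoint topographies
#'
#' @slot k integer(1), number of clusters.
#' @slot centroids numeric matrix, channels x k.
#' @slot labels integer vector, cluster id (1..k) per timepoint.
#' @slot innerDistanceSum numeric(1), sum over timepoints of squared
#'   Euclidean distance to the assigned centroid.
#' @slot nRestarts integer(1), restarts used.
#' @slot maxIter integer(1), iteration cap per restart.
#' @slot seed integer(1).
#' @slot nReseeds integer(1), restarts re-seeded because a cluster emptied.
#'
#' @export
setClass("ClusterModel",
  representation(
    k = "integer",
    centroids = "matrix",
    labels = "integer",
    innerDistanceSum = "numeric",
    nRestarts = "integer",
    maxIter = "integer",
    seed = "integer",
    nReseeds = "integer"
  )
)

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (ncol(object@centroids) != object@k) {
    msg <- c(msg, "'centroids' must have k columns")
  }
  if (any(object@labels < 1L) || any(object@labels > object@k)) {
    msg <- c(msg, "labels must lie in 1..k")
  }
  if (object@innerDistanceSum < 0) {
    msg <- c(msg, "'innerDistanceSum' must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Segmentation: microstates as maximal runs of cluster labels
#'
#' @slot microstates data.frame with columns `index`, `start_ms`, `end_ms`,
#'   `cluster_id`; ordered, contiguous, covering the window. Intervals are
#'   half-open `[start_ms, end_ms)` on the sampling grid.
#' @slot window numeric(2).
#' @slot timesMs numeric, the sampling grid the labels were defined on.
#'
#' @export
setClass("Segmentation",
  representation(
    microstates = "data.frame",
    window = "numeric",
    timesMs = "numeric"
  )
)

setValidity("Segmentation", function(object) {
  ms <- object@microstates
  need <- c("index", "start_ms", "end_ms", "cluster_id")
  if (!all(need %in% names(ms))) {
    return("'microstates' must have columns index, start_ms, end_ms, cluster_id")
  }
  msg <- character()
  if (nrow(ms) > 1) {
    if (any(abs(ms$start_ms[-1] - ms$end_ms[-nrow(ms)]) > 1e-9)) {
      msg <- c(msg, "microstates must be contiguous and non-overlapping")
    }
    if (any(ms$cluster_id[-1] == ms$cluster_id[-nrow(ms)])) {
      msg <- c(msg, "adjacent microstates must have different cluster ids")
    }
  }
  if (length(msg)) msg else TRUE
})

#' TanovaResult: permutation TANOVA outcome for one condition comparison
#'
#' @slot table data.frame, one row per microstate: `microstate`,
#'   `cos_theta_obs`, `p_value`, `significant`.
#' @slot null numeric matrix, permutations x microstates, the cosine null
#'   distribution.
#' @slot alphaAdj numeric(1), Bonferroni-adjusted significance level.
#' @slot nPerm integer(1).
#' @slot seed integer(1).
#' @slot comparison character(2), the condition labels compared.
#'
#' @export
setClass("TanovaResult",
  representation(
    table = "data.frame",
    null = "matrix",
    alphaAdj = "numeric",
    nPerm = "integer",
    seed = "integer",
    comparison = "character"
  )
)

setValidity("TanovaResult", function(object) {
  msg <- character()
  tb <- object@table
  if (nrow(object@null) != object@nPerm) {
    msg <- c(msg, "null matrix must have nPerm rows")
  }
  if (ncol(object@null) != nrow(tb)) {
    msg <- c(msg, "null matrix must have one column per microstate")
  }
  rng <- range(c(tb$cos_theta_obs, object@null), na.rm = TRUE)
  if (length(object@null) && (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9)) {
    msg <- c(msg, "cosine values must lie in [-1, 1]")
  }
  if (any(tb$p_value <= 0 | tb$p_value > 1)) {
    msg <- c(msg, "p-values must lie in (0, 1]")
  }
  if (!identical(as.logical(tb$significant),
                 as.logical(tb$p_value < object@alphaAdj))) {
    msg <- c(msg, "'significant' must equal p_value < alphaAdj")
  }
  if (length(msg)) msg else TRUE
})

#' PosthocTable: channel-wise paired t-test results
#'
#' @slot table data.frame, one row per tested microstate x channel:
#'   `microstate`, `channel`, `t`, `p_value`, `direction` (sign of
#'   mean(A - B)), `significant`, `degenerate`.
#' @slot alphaAdj numeric(1), alpha / number of channels.
#' @slot seed integer(1), the epoch-equalization seed.
#' @slot nEqualized integer(1), epochs per condition after equalization.
#'
#' @export
setClass("PosthocTable",
  representation(
    table = "data.frame",
    alphaAdj = "numeric",
    seed = "integer",
    nEqualized = "integer"
  )
)

setValidity("PosthocTable", function(object) {
  tb <- object@table
  need <- c("microstate", "channel", "t", "p_value", "direction",
            "significant", "degenerate")
  if (!all(need %in% names(tb))) {
    return(paste("'table' must have columns", paste(need, collapse = ", ")))
  }
  ok <- is.na(tb$p_value) | tb$significant == (tb$p_value < object@alphaAdj)
  if (!all(ok)) {
    return("'significant' must equal p_value < alphaAdj")
  }
  TRUE
})
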