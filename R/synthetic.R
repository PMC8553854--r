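## Synthetic epoch generator: piecewise-stationary template topographies with
## controlled between-condition angular effects, so every downstream stage has
## a ground truth to be checked against.

.deriveSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[i])) %% 2147483647
  }
  as.integer(s)
}

.unitGFP <- function(v) {
  g <- computeGFP(v)
  if (g == 0) stop("degenerate (constant) vector cannot be normalized")
  v / g
}

#' Generate a set of mutually separated template topographies
#'
#' Draws `nTemplates` random channel-space vectors, each scaled to unit GFP,
#' such that every pair is separated by at least `minAngleDeg` degrees
#' (i.e. pairwise `|cos theta| <= cos(minAngleDeg)`). For separations below
#' 90 degrees candidates violating the separation are rejected; at exactly
#' 90 degrees a mutually orthogonal set is constructed directly (QR), since
#' rejection sampling cannot hit a measure-zero event. If the space cannot
#' accommodate the request the function fails explicitly rather than
#' retrying forever.
#'
#' @param nTemplates number of templates (>= 1).
#' @param nChannels number of channels (>= 2).
#' @param minAngleDeg minimum pairwise angular separation in degrees,
#'   in (0, 90].
#' @param seed integer seed; the result is deterministic given the seed.
#' @param maxTries rejection attempts per template before giving up.
#' @return a [TemplateSet-class].
#' @examples
#' ts <- makeTemplates(3, 30, 60, seed = 1)
#' round(crossprod(templates(ts)) / 30, 2)  # pairwise cosines
#' @export
makeTemplates <- function(nTemplates, nChannels, minAngleDeg = 60,
                          seed = 1L, maxTries = 5000L) {
  stopifnot(nTemplates >= 1, nChannels >= 2,
            minAngleDeg > 0, minAngleDeg <= 90)
  maxCos <- cos(minAngleDeg * pi / 180)
  set.seed(as.integer(seed))
  if (minAngleDeg == 90) {
    if (nTemplates > nChannels) {
      stop(sprintf(
        "cannot place %d mutually orthogonal templates in %d channels",
        nTemplates, nChannels))
    }
    q <- qr.Q(qr(matrix(stats::rnorm(nChannels * nTemplates),
                        nChannels, nTemplates)))
    # rescaling columns to unit GFP preserves pairwise orthogonality
    out <- apply(q, 2, .unitGFP)
    out <- matrix(out, nChannels, nTemplates)
  } else {
    out <- matrix(0, nChannels, nTemplates)
    for (j in seq_len(nTemplates)) {
      ok <- FALSE
      for (try in seq_len(maxTries)) {
        cand <- .unitGFP(stats::rnorm(nChannels))
        if (j == 1L) { ok <- TRUE }
        else {
          prev <- out[, seq_len(j - 1L), drop = FALSE]
          cosines <- crossprod(prev, cand) /
            (sqrt(colSums(prev^2)) * sqrt(sum(cand^2)))
          ok <- all(abs(cosines) <= maxCos + 1e-12)
        }
        if (ok) { out[, j] <- cand; break }
      }
      if (!ok) {
        stop(sprintf(
          "could not place template %d of %d at >= %g deg separation in %d channels after %d tries; the request is infeasible or nearly so",
          j, nTemplates, minAngleDeg, nChannels, maxTries))
      }
    }
  }
  labels <- paste0("T", seq_len(nTemplates))
  colnames(out) <- labels
  rownames(out) <- if (nChannels == 30) defaultMontage()
                   else paste0("ch", seq_len(nChannels))
  new("TemplateSet", templates = out, labels = labels,
      minAngleDeg = minAngleDeg)
}

#' Pairwise cosine similarities of a template set
#'
#' @param templateSet a [TemplateSet-class].
#' @return symmetric matrix of pairwise cos theta values.
#' @export
templateCosines <- function(templateSet) {
  tm <- templateSet@templates
  nrm <- sqrt(colSums(tm^2))
  crossprod(tm) / tcrossprod(nrm)
}

#' Build a microstate timeline from explicit segments
#'
#' @param templateIds character or integer ids, one per segment (adjacent ids
#'   must differ).
#' @param durationsMs numeric segment durations in ms; must tile the window
#'   exactly.
#' @param t0Ms window start (default 0).
#' @return a [Timeline-class] over `[t0Ms, t0Ms + sum(durationsMs))`.
#' @export
makeTimeline <- function(templateIds, durationsMs, t0Ms = 0) {
  stopifnot(length(templateIds) == length(durationsMs), all(durationsMs > 0))
  ends <- t0Ms + cumsum(durationsMs)
  starts <- c(t0Ms, ends[-length(ends)])
  seg <- data.frame(start_ms = starts, end_ms = ends,
                    template_id = as.character(templateIds),
                    stringsAsFactors = FALSE)
  new("Timeline", segments = seg, window = c(t0Ms, ends[length(ends)]))
}

#' Tile a window with fixed-duration segments cycling through templates
#'
#' Convenience constructor: segments of `durationMs` (default 100 ms, inside
#' the conventional 60-120 ms range of resting-state microstate durations)
#' cycling through the template labels; a shorter final segment absorbs any
#' remainder.
#'
#' @param templateLabels character vector of template ids to cycle through
#'   (or a [TemplateSet-class]).
#' @param window numeric(2) half-open window in ms (default `c(0, 600)`).
#' @param durationMs segment duration in ms (default 100).
#' @return a [Timeline-class].
#' @export
tileTimeline <- function(templateLabels, window = c(0, 600),
                         durationMs = 100) {
  if (is(templateLabels, "TemplateSet")) {
    templateLabels <- templateLabels@labels
  }
  stopifnot(durationMs > 0, length(templateLabels) >= 1)
  span <- window[2] - window[1]
  nFull <- floor(span / durationMs)
  durs <- rep(durationMs, nFull)
  rem <- span - nFull * durationMs
  if (rem > 1e-9) durs <- c(durs, rem)
  if (length(durs) > 1 && length(templateLabels) == 1) {
    stop("cannot tile more than one segment with a single template (adjacent segments must differ)")
  }
  ids <- rep_len(templateLabels, length(durs))
  makeTimeline(ids, durs, t0Ms = window[1])
}

#' Specify a between-condition topographic effect
#'
#' @param affectedSegments integer segment indices carrying the effect.
#' @param angleDeg angular perturbation (degrees, in `[0, 180]`) of the
#'   affected templates in condition B relative to A.
#' @param amplitudeRatio GFP-envelope scaling for condition B in the affected
#'   segments (default 1).
#' @return an [EffectSpec-class].
#' @export
effectSpec <- function(affectedSegments = integer(), angleDeg = 0,
                       amplitudeRatio = 1) {
  new("EffectSpec", affectedSegments = as.integer(affectedSegments),
      angleDeg = as.numeric(angleDeg),
      amplitudeRatio = as.numeric(amplitudeRatio))
}

#' Default ERP-like GFP envelope
#'
#' A smooth, strictly positive amplitude waveform in microvolts: a 2 uV floor
#' plus an early sharp component around 180 ms and a broader late component
#' around 400 ms, loosely shaped like the GFP of a visual ERP.
#'
#' @param timesMs numeric time axis in ms.
#' @return numeric envelope (uV), same length as `timesMs`.
#' @export
defaultEnvelope <- function(timesMs) {
  2 + 8 * exp(-((timesMs - 180) / 60)^2) +
      5 * exp(-((timesMs - 400) / 120)^2)
}

#' Construct a TruthManifest
#'
#' Bundles everything that determines a synthetic dataset. The defaults mirror
#' the emulated study design: 30 scalp channels sampled at 250 Hz over a
#' half-open `[0, 600)` ms window, 107 subjects with 16 retained epochs per
#' condition, and single-trial noise much larger than the signal so that
#' averaging across epochs is what makes the ERP emerge.
#'
#' @param templateSet a [TemplateSet-class] (default: 4 templates on the
#'   30-channel montage at >= 60 degrees separation, seeded from `seed`).
#' @param timeline a [Timeline-class] (default: 100 ms tiling of the window).
#' @param effect an [EffectSpec-class] (default: no effect).
#' @param nSubjects number of subjects (default 107).
#' @param nEpochsPerCondition retained epochs per subject and condition
#'   (default 16).
#' @param noiseSd single-trial additive noise sd in uV (default 10).
#' @param subjectSd sd of per-subject additive template jitter on the
#'   unit-GFP template scale (default 0.1).
#' @param envelope GFP waveform in uV per timepoint (default
#'   [defaultEnvelope()]).
#' @param window numeric(2) half-open analysis window in ms (default
#'   `c(0, 600)`).
#' @param samplingRate Hz (default 250).
#' @param seed master seed.
#' @return a [TruthManifest-class].
#' @export
truthManifest <- function(templateSet = NULL, timeline = NULL,
                          effect = effectSpec(), nSubjects = 107,
                          nEpochsPerCondition = 16, noiseSd = 10,
                          subjectSd = 0.1, envelope = NULL,
                          window = c(0, 600), samplingRate = 250,
                          seed = 1L) {
  if (is.null(templateSet)) {
    templateSet <- makeTemplates(4, 30, 60, seed = .deriveSeed(seed, 1L))
  }
  if (is.null(timeline)) {
    timeline <- tileTimeline(templateSet, window = window)
  }
  tms <- windowTimes(timeline@window, samplingRate)
  if (is.null(envelope)) envelope <- defaultEnvelope(tms)
  new("TruthManifest", templateSet = templateSet, timeline = timeline,
      effectSpec = effect, nSubjects = as.integer(nSubjects),
      nEpochsPerCondition = as.integer(nEpochsPerCondition),
      noiseSd = as.numeric(noiseSd), subjectSd = as.numeric(subjectSd),
      envelope = as.numeric(envelope),
      samplingRate = as.numeric(samplingRate), seed = as.integer(seed))
}

# Map each timepoint of the grid to its (half-open) timeline segment index.
.segmentOfTimes <- function(timeline, timesMs) {
  seg <- timeline@segments
  idx <- rep(NA_integer_, length(timesMs))
  for (s in seq_len(nrow(seg))) {
    idx[timesMs >= seg$start_ms[s] - 1e-9 &
        timesMs < seg$end_ms[s] - 1e-9] <- s
  }
  if (anyNA(idx)) stop("time axis extends beyond the timeline window")
  idx
}

# Perturb a unit-GFP topography `v` so that cos(v, result) = cos(angleDeg)
# exactly and the result again has unit GFP. The perturbation direction `u`
# is derived from `axis`, made zero-mean and orthogonal to v (two linear
# constraints, so at least 3 channels are required), and scaled to unit GFP.
# With r = alpha*v + beta*u, beta^2 = 1 - alpha^2 gives GFP(r) = 1 (the
# cross-covariance vanishes), and alpha = c / sqrt(1 + m^2*(1 - c^2)) with
# c = cos(angleDeg), m = mean(v) makes the raw cosine exactly c.
.rotateTopography <- function(v, angleDeg, axis) {
  if (length(v) < 3) {
    stop("angular perturbation requires at least 3 channels")
  }
  vt <- v - mean(v)  # v orthogonalized against the constant vector
  u <- axis - mean(axis)
  u <- u - (sum(u * vt) / sum(vt * vt)) * vt
  g <- sqrt(mean(u^2))
  if (g < 1e-12) stop("rotation axis is collinear with the template")
  u <- u / g
  cc <- cos(angleDeg * pi / 180)
  m <- mean(v)
  alpha <- cc / sqrt(1 + m^2 * (1 - cc^2))
  beta <- sqrt(max(0, 1 - alpha^2))
  alpha * v + beta * u
}

#' Simulate a single epoch from a timeline
#'
#' At every timepoint `t` in segment `s`, the expected topography is
#' `envelope(t) * template(s)`; independent zero-mean Gaussian noise of sd
#' `noiseSd` is added per channel and timepoint (optionally spatially
#' correlated via a channel covariance matrix).
#'
#' @param timeline a [Timeline-class].
#' @param templateSet a [TemplateSet-class] whose labels cover the timeline's
#'   template ids.
#' @param envelope numeric GFP waveform, one value per timepoint of the
#'   window grid.
#' @param noiseSd noise standard deviation in uV.
#' @param seed integer seed.
#' @param samplingRate Hz (default 250).
#' @param noiseCov optional channels x channels covariance matrix for
#'   spatially correlated noise; overrides `noiseSd`.
#' @return numeric matrix, channels x timepoints.
#' @export
simulateEpoch <- function(timeline, templateSet, envelope, noiseSd = 0,
                          seed = 1L, samplingRate = 250, noiseCov = NULL) {
  tms <- windowTimes(timeline@window, samplingRate)
  if (length(envelope) != length(tms)) {
    stop(sprintf("envelope length (%d) must equal the %d timepoints of the window",
                 length(envelope), length(tms)))
  }
  ids <- timeline@segments$template_id
  missing <- setdiff(ids, templateSet@labels)
  if (length(missing)) {
    stop("timeline references unknown template id(s): ",
         paste(missing, collapse = ", "))
  }
  segIdx <- .segmentOfTimes(timeline, tms)
  tmpl <- templateSet@templates[, match(ids, templateSet@labels),
                                drop = FALSE]
  signal <- tmpl[, segIdx, drop = FALSE] *
    rep(envelope, each = nrow(tmpl))
  set.seed(as.integer(seed))
  nCh <- nrow(tmpl)
  if (is.null(noiseCov)) {
    noise <- matrix(stats::rnorm(nCh * length(tms), sd = noiseSd),
                    nCh, length(tms))
  } else {
    stopifnot(nrow(noiseCov) == nCh, ncol(noiseCov) == nCh)
    z <- matrix(stats::rnorm(nCh * length(tms)), nCh, length(tms))
    noise <- t(chol(noiseCov)) %*% z
  }
  out <- signal + noise
  rownames(out) <- rownames(templateSet@templates)
  out
}

#' Simulate a full multi-subject, two-condition dataset
#'
#' Produces one [EpochSet-class] per subject x condition. Per subject, each
#' template receives additive Gaussian jitter of sd `subjectSd` (then is
#' re-centered and rescaled to unit GFP); condition A uses the subject's
#' templates as-is, while condition B rotates the templates of the affected
#' segments by the effect angle (within a plane fixed by the master seed, so
#' the angular displacement is identical across subjects) and scales the
#' envelope there by the amplitude ratio. Epoch noise is drawn independently
#' per epoch. Bit-reproducible given the manifest.
#'
#' @param manifest a [TruthManifest-class].
#' @param conditionLabels character(2), labels for the two conditions
#'   (default `c("A", "B")`).
#' @return a list with elements `epochSets` (list of [EpochSet-class], named
#'   `subject.condition`) and `manifest` (the input, echoed).
#' @export
simulateDataset <- function(manifest, conditionLabels = c("A", "B")) {
  validObject(manifest)
  tl <- manifest@timeline
  ts <- manifest@templateSet
  eff <- manifest@effectSpec
  tms <- windowTimes(tl@window, manifest@samplingRate)
  nCh <- nrow(ts@templates)
  nSeg <- nrow(tl@segments)
  segTemplateIdx <- match(tl@segments$template_id, ts@labels)

  # one fixed rotation axis per affected segment, from the master seed
  set.seed(.deriveSeed(manifest@seed, 7L))
  axes <- matrix(stats::rnorm(nCh * nSeg), nCh, nSeg)

  envB <- manifest@envelope
  segIdx <- .segmentOfTimes(tl, tms)
  if (length(eff@affectedSegments)) {
    affTp <- segIdx %in% eff@affectedSegments
    envB[affTp] <- envB[affTp] * eff@amplitudeRatio
  }

  subjIds <- sprintf("S%02d", seq_len(manifest@nSubjects))
  out <- vector("list", manifest@nSubjects * 2L)
  nm <- character(length(out))
  k <- 0L
  for (i in seq_len(manifest@nSubjects)) {
    # per-subject template jitter (sd on the unit-GFP scale)
    set.seed(.deriveSeed(manifest@seed, 11L, i))
    subjTemplates <- ts@templates
    if (manifest@subjectSd > 0) {
      jit <- matrix(stats::rnorm(length(subjTemplates),
                                 sd = manifest@subjectSd),
                    nrow(subjTemplates), ncol(subjTemplates))
      subjTemplates <- apply(subjTemplates + jit, 2, .unitGFP)
    }
    # per-segment topographies for each condition
    topoA <- subjTemplates[, segTemplateIdx, drop = FALSE]
    topoB <- topoA
    for (s in eff@affectedSegments) {
      topoB[, s] <- .rotateTopography(topoA[, s], eff@angleDeg, axes[, s])
    }
    for (condI in 1:2) {
      topo <- if (condI == 1L) topoA else topoB
      env <- if (condI == 1L) manifest@envelope else envB
      signal <- topo[, segIdx, drop = FALSE] * rep(env, each = nCh)
      arr <- array(0, dim = c(manifest@nEpochsPerCondition, nCh,
                              length(tms)))
      for (e in seq_len(manifest@nEpochsPerCondition)) {
        set.seed(.deriveSeed(manifest@seed, 13L, i, condI, e))
        arr[e, , ] <- signal +
          matrix(stats::rnorm(nCh * length(tms), sd = manifest@noiseSd),
                 nCh, length(tms))
      }
      k <- k + 1L
      out[[k]] <- new("EpochSet", subjectId = subjIds[i],
                      condition = conditionLabels[condI], data = arr,
                      timesMs = tms, montage = rownames(ts@templates) %||%
                        paste0("ch", seq_len(nCh)),
                      samplingRate = manifest@samplingRate)
      nm[k] <- paste(subjIds[i], conditionLabels[condI], sep = ".")
    }
  }
  names(out) <- nm
  list(epochSets = out, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
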