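## Plain-text interchange: epoch bundles (one TSV matrix per epoch + JSON
## manifest), truth-manifest JSON, BrainVision ASCII exports, and CSV/JSON
## writers for diagnostics and results.

#' Write an EpochSet as a plain-text epoch bundle
#'
#' One tab-separated channels x timepoints matrix (microvolts, no headers)
#' per epoch, plus `manifest.json` describing subject, condition, montage,
#' sampling rate, window and the epoch file names.
#'
#' @param epochSet an [EpochSet-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeEpochBundle <- function(epochSet, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nEpochs(epochSet)
  files <- sprintf("epoch_%04d.tsv", seq_len(n))
  for (e in seq_len(n)) {
    utils::write.table(epochSet@data[e, , ], file.path(dir, files[e]),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(
    subject = epochSet@subjectId,
    condition = epochSet@condition,
    montage = epochSet@montage,
    sampling_rate_hz = epochSet@samplingRate,
    times_ms = epochSet@timesMs,
    epoch_files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an epoch bundle back into an EpochSet
#'
#' @param dir a directory written by [writeEpochBundle()].
#' @return an [EpochSet-class].
#' @export
readEpochBundle <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  mats <- lapply(mf$epoch_files, function(f) {
    as.matrix(utils::read.table(file.path(dir, f), sep = "\t"))
  })
  arr <- array(0, dim = c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])))
  for (e in seq_along(mats)) arr[e, , ] <- mats[[e]]
  new("EpochSet", subjectId = mf$subject, condition = mf$condition,
      data = arr, timesMs = as.numeric(mf$times_ms),
      montage = as.character(mf$montage),
      samplingRate = as.numeric(mf$sampling_rate_hz))
}

#' Serialize a TruthManifest to JSON (and back)
#'
#' The JSON carries templates, timeline, effect, counts, noise parameters,
#' envelope and seed -- everything needed to regenerate the dataset
#' bit-identically.
#'
#' @param manifest a [TruthManifest-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTruthManifest <- function(manifest, path) {
  obj <- list(
    templates = manifest@templateSet@templates,
    template_labels = manifest@templateSet@labels,
    template_montage = rownames(manifest@templateSet@templates),
    min_angle_deg = manifest@templateSet@minAngleDeg,
    segments = manifest@timeline@segments,
    window_ms = manifest@timeline@window,
    affected_segments = manifest@effectSpec@affectedSegments,
    angle_deg = manifest@effectSpec@angleDeg,
    amplitude_ratio = manifest@effectSpec@amplitudeRatio,
    n_subjects = manifest@nSubjects,
    n_epochs_per_condition = manifest@nEpochsPerCondition,
    noise_sd = manifest@noiseSd,
    subject_sd = manifest@subjectSd,
    envelope = manifest@envelope,
    sampling_rate_hz = manifest@samplingRate,
    seed = manifest@seed
  )
  # digits = I(17): decimal-exact round trip, so a reread manifest
  # regenerates the dataset bit-identically
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writeTruthManifest
#' @export
readTruthManifest <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  tm <- as.matrix(o$templates)
  rownames(tm) <- o$template_montage
  colnames(tm) <- o$template_labels
  ts <- new("TemplateSet", templates = tm,
            labels = as.character(o$template_labels),
            minAngleDeg = o$min_angle_deg)
  tl <- new("Timeline", segments = as.data.frame(o$segments),
            window = as.numeric(o$window_ms))
  eff <- effectSpec(o$affected_segments, o$angle_deg, o$amplitude_ratio)
  new("TruthManifest", templateSet = ts, timeline = tl, effectSpec = eff,
      nSubjects = as.integer(o$n_subjects),
      nEpochsPerCondition = as.integer(o$n_epochs_per_condition),
      noiseSd = as.numeric(o$noise_sd), subjectSd = as.numeric(o$subject_sd),
      envelope = as.numeric(o$envelope),
      samplingRate = as.numeric(o$sampling_rate_hz),
      seed = as.integer(o$seed))
}

# Parse the INI-like sections of a BrainVision header/marker file.
.parseIni <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- ""
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && nzchar(section)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <-
        trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' Read a BrainVision ASCII export
#'
#' Minimal reader for BrainVision Core triplets whose data file is a plain
#' ASCII export in multiplexed orientation (rows = samples, columns =
#' channels). Binary data files are not supported. Markers (from the `.vmrk`
#' file, when present) are returned as a table of type, description and
#' sample position.
#'
#' @param vhdrPath path to the `.vhdr` header file.
#' @return list with `data` (channels x samples matrix), `montage`,
#'   `samplingRate` (Hz) and `markers` (data.frame or NULL).
#' @export
readBrainVisionAscii <- function(vhdrPath) {
  hdr <- .parseIni(readLines(vhdrPath, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: no [Common Infos] section")
  if (!is.null(ci$DataFormat) && toupper(ci$DataFormat) != "ASCII") {
    stop("only ASCII data files are supported (DataFormat=",
         ci$DataFormat, ")")
  }
  orientation <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  nCh <- as.integer(ci$NumberOfChannels)
  sr <- 1e6 / as.numeric(ci$SamplingInterval)  # interval is in microseconds
  chInfo <- hdr[["Channel Infos"]]
  montage <- if (!is.null(chInfo)) {
    vapply(chInfo, function(v) strsplit(v, ",")[[1]][1], character(1))
  } else paste0("ch", seq_len(nCh))
  dataFile <- file.path(dirname(vhdrPath), ci$DataFile)
  skip <- as.integer(hdr[["ASCII Infos"]]$SkipLines %||% "0")
  raw <- as.matrix(utils::read.table(dataFile, skip = skip))
  data <- if (orientation == "MULTIPLEXED") t(raw) else raw
  if (nrow(data) != nCh) {
    stop(sprintf("data file has %d channels, header declares %d",
                 nrow(data), nCh))
  }
  rownames(data) <- montage
  markers <- NULL
  if (!is.null(ci$MarkerFile)) {
    mrkPath <- file.path(dirname(vhdrPath), ci$MarkerFile)
    if (file.exists(mrkPath)) {
      mrk <- .parseIni(readLines(mrkPath, warn = FALSE))[["Marker Infos"]]
      if (!is.null(mrk)) {
        parts <- lapply(mrk, function(v) strsplit(v, ",")[[1]])
        markers <- data.frame(
          type = vapply(parts, `[`, character(1), 1),
          description = vapply(parts, `[`, character(1), 2),
          sample = as.integer(vapply(parts, `[`, character(1), 3))
        )
      }
    }
  }
  list(data = data, montage = unname(montage), samplingRate = sr,
       markers = markers)
}

#' Cut a continuous recording into an EpochSet
#'
#' @param data channels x samples matrix.
#' @param onsets integer sample indices of the stimulus onsets (1-based).
#' @param window numeric(2) half-open window in ms relative to onset.
#' @param samplingRate Hz.
#' @param montage channel labels (default: rownames).
#' @param subjectId,condition labels for the resulting set.
#' @return an [EpochSet-class].
#' @export
epochsFromContinuous <- function(data, onsets, window, samplingRate,
                                 montage = rownames(data),
                                 subjectId = "S01", condition = "A") {
  tms <- windowTimes(window, samplingRate)
  offsets <- round(tms / 1000 * samplingRate)
  arr <- array(0, dim = c(length(onsets), nrow(data), length(tms)))
  for (e in seq_along(onsets)) {
    idx <- onsets[e] + offsets
    if (min(idx) < 1 || max(idx) > ncol(data)) {
      stop(sprintf("epoch %d extends beyond the recording", e))
    }
    arr[e, , ] <- data[, idx]
  }
  new("EpochSet", subjectId = subjectId, condition = condition, data = arr,
      timesMs = tms, montage = montage %||% paste0("ch", seq_len(nrow(data))),
      samplingRate = samplingRate)
}

#' Result and diagnostic writers
#'
#' Thin CSV/JSON/TSV writers for the pipeline outputs: the k-sweep table, a
#' segmentation, centroid topographies keyed by montage label, a TANOVA
#' table (optionally with its full null), and a post-hoc table.
#'
#' @param x the object to write (see the individual functions).
#' @param path output file.
#' @param includeNull logical, also embed the full null distribution
#'   (TANOVA JSON only).
#' @return the path, invisibly.
#' @name resultWriters
NULL

#' @rdname resultWriters
#' @export
writeSweepCSV <- function(x, path) {
  utils::write.csv(x$summary, path, row.names = FALSE)
  invisible(path)
}

#' @rdname resultWriters
#' @export
writeSegmentationJSON <- function(x, path) {
  stopifnot(is(x, "Segmentation"))
  jsonlite::write_json(
    list(window_ms = x@window, microstates = x@microstates),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname resultWriters
#' @param centroidMatrix channels x clusters matrix with montage rownames.
#' @export
writeCentroidsTSV <- function(centroidMatrix, path) {
  utils::write.table(centroidMatrix, path, sep = "\t", col.names = NA,
                     quote = FALSE)
  invisible(path)
}

#' @rdname resultWriters
#' @export
writeTanovaCSV <- function(x, path) {
  stopifnot(is(x, "TanovaResult"))
  tb <- x@table
  tb$alpha_adj <- round(x@alphaAdj, 4)
  utils::write.csv(tb, path, row.names = FALSE)
  invisible(path)
}

#' @rdname resultWriters
#' @export
writeTanovaJSON <- function(x, path, includeNull = FALSE) {
  stopifnot(is(x, "TanovaResult"))
  obj <- list(comparison = x@comparison, table = x@table,
              alpha_adj = x@alphaAdj, n_permutations = x@nPerm,
              seed = x@seed)
  if (includeNull) obj$null <- x@null
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname resultWriters
#' @export
writePosthocCSV <- function(x, path) {
  stopifnot(is(x, "PosthocTable"))
  tb <- x@table
  tb$alpha_adj <- round(x@alphaAdj, 4)
  utils::write.csv(tb, path, row.names = FALSE)
  invisible(path)
}
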