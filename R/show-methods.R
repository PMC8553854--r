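setMethod("show", "TemplateSet", function(object) {
  cat(sprintf("TemplateSet: %d templates x %d channels (min separation %g deg)\n",
              ncol(object@templates), nrow(object@templates),
              object@minAngleDeg))
})

setMethod("show", "Timeline", function(object) {
  cat(sprintf("Timeline: %d segments over [%g, %g) ms\n",
              nrow(object@segments), object@window[1], object@window[2]))
  print(object@segments)
})

setMethod("show", "TruthManifest", function(object) {
  cat(sprintf(
    "TruthManifest: %d subjects x 2 conditions, %d epochs/condition\n",
    object@nSubjects, object@nEpochsPerCondition))
  cat(sprintf("  %d templates, %d segments, noise sd %g uV, subject sd %g, seed %d\n",
              ncol(object@templateSet@templates),
              nrow(object@timeline@segments), object@noiseSd,
              object@subjectSd, object@seed))
  eff <- object@effectSpec
  if (length(eff@affectedSegments)) {
    cat(sprintf("  effect: %g deg rotation (amplitude ratio %g) in segment(s) %s\n",
                eff@angleDeg, eff@amplitudeRatio,
                paste(eff@affectedSegments, collapse = ", ")))
  } else {
    cat("  effect: none (null configuration)\n")
  }
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet %s/%s: %d epochs x %d channels x %d timepoints (%g Hz)\n",
              object@subjectId, object@condition, d[1], d[2], d[3],
              object@samplingRate))
})

setMethod("show", "ERPMatrix", function(object) {
  cat(sprintf("ERPMatrix [%s]: %d channels x %d timepoints, %s\n",
              object@provenance, nrow(object@data), ncol(object@data),
              if (object@normalized) "GFP-normalized" else "in uV"))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k = %d, inner distance sum = %.6g (%d restarts, %d reseeds)\n",
              object@k, object@innerDistanceSum, object@nRestarts,
              object@nReseeds))
})

setMethod("show", "Segmentation", function(object) {
  cat(sprintf("Segmentation: %d microstates over [%g, %g) ms\n",
              nrow(object@microstates), object@window[1], object@window[2]))
  print(object@microstates)
})

setMethod("show", "TanovaResult", function(object) {
  cat(sprintf("TANOVA %s vs %s: %d permutations, alpha_adj = %.4f\n",
              object@comparison[1], object@comparison[2], object@nPerm,
              object@alphaAdj))
  print(object@table, digits = 4)
})

setMethod("show", "PosthocTable", function(object) {
  nSig <- sum(object@table$significant, na.rm = TRUE)
  cat(sprintf("PosthocTable: %d tests, %d significant at alpha_adj = %.4f (n = %d epochs/condition)\n",
              nrow(object@table), nSig, object@alphaAdj, object@nEqualized))
})
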