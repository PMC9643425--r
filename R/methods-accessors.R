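## Accessor and show methods.

#' @rdname accessors
setMethod("intensities", "BleachTrace", function(object) object@intensities)
#' @rdname accessors
setMethod("frameInterval", "BleachTrace", function(object) object@frameInterval)
#' @rdname accessors
setMethod("groundTruthSteps", "BleachTrace",
          function(object) object@groundTruthSteps)
#' @rdname accessors
setMethod("nFrames", "BleachTrace", function(object) length(object@intensities))

#' @rdname accessors
setMethod("stepCounts", "StepCountHistogram", function(object) object@counts)
#' @rdname accessors
setMethod("nSpots", "StepCountHistogram",
          function(object) sum(object@counts))

#' @rdname accessors
setMethod("nSubunits", "OligomerFit", function(object) object@nSubunits)
#' @rdname accessors
setMethod("pHat", "OligomerFit", function(object) object@pHat)
#' @rdname accessors
setMethod("chisqStat", "OligomerFit", function(object) object@chisq)
#' @rdname accessors
setMethod("pValue", "OligomerFit", function(object) object@pValue)
#' @rdname accessors
setMethod("isRetained", "OligomerFit", function(object) object@retained)

#' @rdname accessors
setMethod("perSegment", "ConsistencyScore", function(object) object@perSegment)
#' @rdname accessors
setMethod("overallScore", "ConsistencyScore", function(object) object@overall)

#' @rdname accessors
setMethod("nPoses", "DockingPoseSet", function(object) length(object@coords))
#' @rdname accessors
setMethod("poseCoords", "DockingPoseSet", function(object) object@coords)
#' @rdname accessors
setMethod("poseRanks", "DockingPoseSet", function(object) object@rank)
#' @rdname accessors
setMethod("affinities", "DockingPoseSet", function(object) object@affinity)
#' @rdname accessors
setMethod("trueClusters", "DockingPoseSet", function(object) object@trueCluster)

#' @rdname accessors
setMethod("typeAssignments", "PoseClustering",
          function(object) object@assignments)
#' @rdname accessors
setMethod("nTypes", "PoseClustering",
          function(object) length(unique(object@assignments)))
#' @rdname accessors
setMethod("typeCentroids", "PoseClustering", function(object) object@centroids)

#' @rdname accessors
setMethod("contactResidues", "ContactSet", function(object) object@residues)

setMethod("show", "BleachTrace", function(object) {
  cat("BleachTrace:", nFrames(object), "frames @", object@frameInterval,
      "ms/frame (", format(nFrames(object) * object@frameInterval / 1000,
                           digits = 3), "s )\n")
  if (length(object@groundTruthSteps))
    cat("  ground-truth bleach times (s):",
        paste(format(object@groundTruthSteps, digits = 3), collapse = ", "),
        "\n")
})

setMethod("show", "StepCountHistogram", function(object) {
  cat("StepCountHistogram:", nSpots(object), "spots\n")
  print(object@counts)
})

setMethod("show", "OligomerFit", function(object) {
  cat(sprintf("OligomerFit: n = %d, p_hat = %.4f\n", object@nSubunits,
              object@pHat))
  cat(sprintf("  chisq = %.4g, df = %d (p = %.4g); df without fitted-p = %d (p = %.4g)\n",
              object@chisq, object@df, object@pValue, object@dfAlt,
              object@pValueAlt))
  if (!is.na(object@retained))
    cat("  ", if (object@retained) "retained" else "rejected", "\n")
  if (object@degenerate) cat("  [degenerate fit]\n")
})

setMethod("show", "AlignedPair", function(object) {
  cat("AlignedPair (", object@sourceLabel, "): ", nchar(object@seqA),
      " columns\n", sep = "")
})

setMethod("show", "ConsistencyScore", function(object) {
  cat(sprintf("ConsistencyScore (%s): overall = %.4f over %d segments\n",
              object@method, object@overall, length(object@perSegment)))
})

setMethod("show", "DockingPoseSet", function(object) {
  cat("DockingPoseSet:", nPoses(object), "poses,",
      nrow(object@coords[[1]]), "ligand atoms each\n")
})

setMethod("show", "PoseClustering", function(object) {
  cat("PoseClustering:", nTypes(object), "binding-site types at cutoff",
      object@cutoff, "A\n")
  for (k in seq_len(nTypes(object)))
    cat(sprintf("  type %d: poses #%s\n", k,
                paste(sort(as.integer(names(object@assignments)[
                  object@assignments == k])), collapse = ", #")))
})

setMethod("show", "ContactSet", function(object) {
  cat("ContactSet:", nrow(object@residues), "residues within",
      object@cutoff, "A (", object@definition, ")\n")
})
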