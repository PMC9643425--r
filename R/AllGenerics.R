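#' Accessors for grchannel classes
#'
#' Small accessor generics for the S4 data objects: trace samples and
#' timing, histogram counts, fitted parameters, clustering assignments and
#' contact tables.
#'
#' @param object a grchannel S4 object.
#' @return The slot contents described under each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("groundTruthSteps",
           function(object) standardGeneric("groundTruthSteps"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("stepCounts", function(object) standardGeneric("stepCounts"))
#' @rdname accessors
#' @export
setGeneric("nSpots", function(object) standardGeneric("nSpots"))
#' @rdname accessors
#' @export
setGeneric("nSubunits", function(object) standardGeneric("nSubunits"))
#' @rdname accessors
#' @export
setGeneric("pHat", function(object) standardGeneric("pHat"))
#' @rdname accessors
#' @export
setGeneric("chisqStat", function(object) standardGeneric("chisqStat"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("isRetained", function(object) standardGeneric("isRetained"))
#' @rdname accessors
#' @export
setGeneric("perSegment", function(object) standardGeneric("perSegment"))
#' @rdname accessors
#' @export
setGeneric("overallScore", function(object) standardGeneric("overallScore"))
#' @rdname accessors
#' @export
setGeneric("nPoses", function(object) standardGeneric("nPoses"))
#' @rdname accessors
#' @export
setGeneric("poseCoords", function(object) standardGeneric("poseCoords"))
#' @rdname accessors
#' @export
setGeneric("poseRanks", function(object) standardGeneric("poseRanks"))
#' @rdname accessors
#' @export
setGeneric("affinities", function(object) standardGeneric("affinities"))
#' @rdname accessors
#' @export
setGeneric("trueClusters", function(object) standardGeneric("trueClusters"))
#' @rdname accessors
#' @export
setGeneric("typeAssignments",
           function(object) standardGeneric("typeAssignments"))
#' @rdname accessors
#' @export
setGeneric("nTypes", function(object) standardGeneric("nTypes"))
#' @rdname accessors
#' @export
setGeneric("typeCentroids", function(object) standardGeneric("typeCentroids"))
#' @rdname accessors
#' @export
setGeneric("contactResidues",
           function(object) standardGeneric("contactResidues"))
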