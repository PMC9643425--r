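## S4 classes for the core data objects of the pipeline.

#' Single-spot photobleaching trace
#'
#' A uniformly sampled fluorescence intensity series for one diffraction
#' limited spot, as produced by single-molecule TIRF imaging of a GFP-tagged
#' receptor. Samples are taken at times `(j - 1) * frameInterval / 1000`
#' seconds for frame `j`. Traces simulated by [simulateBleachTrace()] carry
#' their ground-truth bleach times.
#'
#' @slot frameInterval frame interval in milliseconds (> 0).
#' @slot intensities numeric vector of fluorescence intensities (arbitrary
#'   units), at least two samples.
#' @slot groundTruthSteps numeric vector of true bleach-event times in
#'   seconds (possibly empty; empty for experimental traces).
#' @exportClass BleachTrace
setClass("BleachTrace",
  representation(frameInterval = "numeric",
                 intensities = "numeric",
                 groundTruthSteps = "numeric"),
  prototype(frameInterval = 113, intensities = numeric(),
            groundTruthSteps = numeric()))

setValidity("BleachTrace", function(object) {
  msg <- character()
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a positive scalar (ms)")
  if (length(object@intensities) < 2L)
    msg <- c(msg, "a trace needs at least 2 samples")
  if (anyNA(object@intensities))
    msg <- c(msg, "intensities must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct a BleachTrace
#'
#' @param intensities numeric vector of intensities (arbitrary units).
#' @param frameInterval frame interval in milliseconds. Default 113 ms, the
#'   acquisition rate typical of single-molecule TIRF of oocyte membranes.
#' @param groundTruthSteps optional numeric vector of true bleach times (s).
#' @return A [BleachTrace-class] object.
#' @examples
#' tr <- BleachTrace(c(3, 3, 2, 2, 1, 1, 0, 0))
#' nFrames(tr)
#' @export
BleachTrace <- function(intensities, frameInterval = 113,
                        groundTruthSteps = numeric()) {
  new("BleachTrace", frameInterval = as.numeric(frameInterval),
      intensities = as.numeric(intensities),
      groundTruthSteps = as.numeric(sort(groundTruthSteps)))
}

#' Histogram of photobleaching step counts
#'
#' Counts of fluorescent spots by the number of bleaching steps observed
#' (at least 1: spots with zero fluorescent subunits are invisible and never
#' enter the histogram). This is the observable from which the oligomeric
#' state is inferred.
#'
#' @slot counts named integer vector; names are step numbers (>= 1), values
#'   are nonnegative spot counts with positive total.
#' @exportClass StepCountHistogram
setClass("StepCountHistogram", representation(counts = "integer"))

setValidity("StepCountHistogram", function(object) {
  k <- suppressWarnings(as.integer(names(object@counts)))
  msg <- character()
  if (length(object@counts) == 0L || anyNA(k) || any(k < 1L))
    msg <- c(msg, "counts must be named by integer step numbers >= 1")
  if (anyNA(object@counts) || any(object@counts < 0L))
    msg <- c(msg, "counts must be nonnegative integers")
  if (sum(object@counts) <= 0L)
    msg <- c(msg, "total spot count must be positive")
  if (anyDuplicated(k))
    msg <- c(msg, "duplicated step numbers")
  if (length(msg)) msg else TRUE
})

#' Construct a StepCountHistogram
#'
#' @param counts named numeric/integer vector (names = step numbers >= 1) or
#'   an unnamed vector whose i-th element is the count of i-step spots.
#' @return A [StepCountHistogram-class] object.
#' @examples
#' StepCountHistogram(c(`1` = 35, `2` = 182, `3` = 420, `4` = 363))
#' @export
StepCountHistogram <- function(counts) {
  if (is.null(names(counts))) names(counts) <- seq_along(counts)
  cnt <- setNames(as.integer(counts), names(counts))
  o <- order(as.integer(names(cnt)))
  new("StepCountHistogram", counts = cnt[o])
}

#' Fit of one candidate oligomer model to a step-count histogram
#'
#' Produced by [selectOligomer()] (or assembled from [fitP()] and
#' [gofTest()]). Holds the candidate subunit count, the fitted per-subunit
#' fluorescence probability, and the Pearson goodness-of-fit test. Because
#' the degrees of freedom depend on whether `p` was estimated from the same
#' data, both conventions are carried: `df`/`pValue` subtract one degree for
#' the fitted parameter, `dfAlt`/`pValueAlt` do not.
#'
#' @slot nSubunits candidate number of subunits.
#' @slot pHat fitted probability that a subunit's tag is fluorescent.
#' @slot chisq Pearson chi-squared statistic (Inf if an empty expected bin
#'   carries observed mass).
#' @slot df,pValue degrees of freedom and p-value, one df subtracted for the
#'   fitted probability.
#' @slot dfAlt,pValueAlt the convention without the subtraction.
#' @slot retained logical; TRUE if the model was not rejected at the level
#'   used by [selectOligomer()] (NA outside that context).
#' @slot degenerate logical; TRUE if the likelihood maximum sat on the
#'   boundary of (0, 1] or the histogram was otherwise uninformative.
#' @exportClass OligomerFit
setClass("OligomerFit",
  representation(nSubunits = "integer", pHat = "numeric", chisq = "numeric",
                 df = "integer", pValue = "numeric", dfAlt = "integer",
                 pValueAlt = "numeric", retained = "logical",
                 degenerate = "logical"),
  prototype(retained = NA, degenerate = FALSE))

setValidity("OligomerFit", function(object) {
  msg <- character()
  if (object@nSubunits < 1L) msg <- c(msg, "nSubunits must be >= 1")
  if (object@pHat < 0 || object@pHat > 1)
    msg <- c(msg, "pHat must lie in [0, 1]")
  if (is.finite(object@chisq) && object@chisq < 0)
    msg <- c(msg, "chisq must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Gapped pairwise alignment of two protein sequences
#'
#' Two residue strings of equal aligned length with `-` as the gap
#' character, plus a free-text label naming the producing aligner (used for
#' deterministic tie-breaking when ranking alignments).
#'
#' @slot seqA,seqB gapped sequences (equal length, non-empty once degapped).
#' @slot sourceLabel character label, e.g. the aligner name.
#' @exportClass AlignedPair
setClass("AlignedPair",
  representation(seqA = "character", seqB = "character",
                 sourceLabel = "character"),
  prototype(sourceLabel = ""))

setValidity("AlignedPair", function(object) {
  msg <- character()
  if (length(object@seqA) != 1L || length(object@seqB) != 1L)
    msg <- c(msg, "seqA and seqB must each be a single string")
  else {
    if (nchar(object@seqA) != nchar(object@seqB))
      msg <- c(msg, "aligned lengths differ")
    if (gsub("-", "", object@seqA) == "" || gsub("-", "", object@seqB) == "")
      msg <- c(msg, "degapped sequences must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AlignedPair
#'
#' @param seqA,seqB gapped sequence strings of equal length (`-` for gaps).
#' @param sourceLabel optional label for the alignment's origin.
#' @return An [AlignedPair-class] object.
#' @examples
#' alignedPair("A-C", "ABC", "toy")
#' @export
alignedPair <- function(seqA, seqB, sourceLabel = "") {
  new("AlignedPair", seqA = as.character(seqA), seqB = as.character(seqB),
      sourceLabel = as.character(sourceLabel))
}

#' Transmembrane-segment consistency score of an alignment
#'
#' Per-segment positional overlap of paired predicted TM segments across the
#' alignment columns, and their mean. See [tmConsistencyScore()].
#'
#' @slot perSegment numeric vector of per-segment overlaps in \[0, 1\].
#' @slot overall arithmetic mean of `perSegment`.
#' @slot method `"jaccard"` or `"coverage"`.
#' @exportClass ConsistencyScore
setClass("ConsistencyScore",
  representation(perSegment = "numeric", overall = "numeric",
                 method = "character"))

setValidity("ConsistencyScore", function(object) {
  msg <- character()
  if (any(object@perSegment < 0 | object@perSegment > 1, na.rm = TRUE))
    msg <- c(msg, "per-segment scores must lie in [0, 1]")
  if (length(object@perSegment) &&
      !isTRUE(all.equal(object@overall,
                        mean(object@perSegment), tolerance = 1e-12)))
    msg <- c(msg, "overall must equal the mean of perSegment")
  if (length(msg)) msg else TRUE
})

#' A set of docking poses for one ligand
#'
#' Ligand heavy-atom coordinates for each docking pose, with the energetic
#' rank (#1 = most favorable), the predicted affinity, and -- for synthetic
#' fixtures -- the planted cluster label.
#'
#' @slot coords list of numeric matrices (nAtoms x 3, Angstrom), one per
#'   pose; all poses have the same atom count.
#' @slot rank integer pose ranks, unique.
#' @slot affinity numeric affinities in kcal/mol (more negative = more
#'   favorable), non-decreasing in rank.
#' @slot trueCluster integer planted cluster labels (NA when unknown).
#' @exportClass DockingPoseSet
setClass("DockingPoseSet",
  representation(coords = "list", rank = "integer", affinity = "numeric",
                 trueCluster = "integer"))

setValidity("DockingPoseSet", function(object) {
  msg <- character()
  np <- length(object@coords)
  if (np < 1L) msg <- c(msg, "at least one pose required")
  if (length(object@rank) != np || anyDuplicated(object@rank))
    msg <- c(msg, "ranks must be unique, one per pose")
  if (length(object@affinity) != np)
    msg <- c(msg, "one affinity per pose required")
  bad <- vapply(object@coords, function(m)
    !is.matrix(m) || ncol(m) != 3L || nrow(m) < 1L || anyNA(m), logical(1))
  if (any(bad)) msg <- c(msg, "each pose needs an nAtoms x 3 coordinate matrix")
  if (length(msg)) msg else TRUE
})

#' Construct a DockingPoseSet
#'
#' @param coords list of nAtoms x 3 coordinate matrices (Angstrom).
#' @param rank integer ranks; defaults to 1..n in list order.
#' @param affinity affinities in kcal/mol; defaults to NA.
#' @param trueCluster planted cluster labels for synthetic fixtures.
#' @return A [DockingPoseSet-class] object.
#' @export
dockingPoseSet <- function(coords, rank = seq_along(coords),
                           affinity = rep(NA_real_, length(coords)),
                           trueCluster = rep(NA_integer_, length(coords))) {
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  })
  new("DockingPoseSet", coords = coords, rank = as.integer(rank),
      affinity = as.numeric(affinity), trueCluster = as.integer(trueCluster))
}

#' Partition of docking poses into binding-site types
#'
#' Result of [clusterPoses()]. Types are numbered in order of their best
#' (lowest-rank, i.e. energetically most favorable) member, so type 1
#' contains pose #1.
#'
#' @slot assignments integer type id per pose, named by pose rank.
#' @slot centroids K x 3 matrix of cluster centroids (mean of member pose
#'   centroids, Angstrom).
#' @slot cutoff single-linkage distance cutoff used (Angstrom).
#' @exportClass PoseClustering
setClass("PoseClustering",
  representation(assignments = "integer", centroids = "matrix",
                 cutoff = "numeric"))

setValidity("PoseClustering", function(object) {
  msg <- character()
  k <- length(unique(object@assignments))
  if (!all(sort(unique(object@assignments)) == seq_len(k)))
    msg <- c(msg, "type ids must be 1..K")
  if (nrow(object@centroids) != k)
    msg <- c(msg, "one centroid per type required")
  if (length(msg)) msg else TRUE
})

#' Ligand-contact residues of one docking pose
#'
#' Receptor residues whose minimum heavy-atom distance to any ligand heavy
#' atom does not exceed the cutoff. This distance rule is a geometric
#' approximation to interface analysis by buried surface area; the
#' `definition` slot carries that caveat into every report.
#'
#' @slot residues data.frame with columns `chain`, `resno`, `resid`,
#'   `minDist` (Angstrom), one row per contact residue, all `minDist <=
#'   cutoff`.
#' @slot cutoff heavy-atom distance cutoff in Angstrom.
#' @slot definition character note on the contact definition.
#' @exportClass ContactSet
setClass("ContactSet",
  representation(residues = "data.frame", cutoff = "numeric",
                 definition = "character"),
  prototype(definition = paste("heavy-atom minimum distance rule;",
                               "approximation to buried-surface interface analysis")))

setValidity("ContactSet", function(object) {
  need <- c("chain", "resno", "resid", "minDist")
  msg <- character()
  if (!all(need %in% names(object@residues)))
    msg <- c(msg, "residues needs columns chain, resno, resid, minDist")
  else if (nrow(object@residues) &&
           any(object@residues$minDist > object@cutoff + 1e-9))
    msg <- c(msg, "all contact distances must be <= cutoff")
  if (length(msg)) msg else TRUE
})
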