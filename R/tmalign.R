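## Positional-consistency scoring of predicted TM segments across pairwise
## alignments -- the criterion for picking an alignment to model from.

#' Map alignment columns to ungapped residue positions
#'
#' @param aln an [AlignedPair-class].
#' @return data.frame with one row per alignment column: `posA`, `posB`
#'   (1-based positions on the ungapped sequences, `NA` at gaps).
#' @examples
#' mapAlignmentColumns(alignedPair("A-C", "ABC"))
#' @export
mapAlignmentColumns <- function(aln) {
  stopifnot(is(aln, "AlignedPair"))
  chA <- strsplit(aln@seqA, "", fixed = TRUE)[[1]]
  chB <- strsplit(aln@seqB, "", fixed = TRUE)[[1]]
  posA <- ifelse(chA == "-", NA_integer_, cumsum(chA != "-"))
  posB <- ifelse(chB == "-", NA_integer_, cumsum(chB != "-"))
  data.frame(posA = as.integer(posA), posB = as.integer(posB))
}

#' Score an alignment by TM-segment positional consistency
#'
#' Predicted TM segments of the two proteins are paired in order (both
#' receptors have seven, S1--S7). For segment pair i, the default score is
#' the Jaccard overlap across alignment columns: the number of columns whose
#' residues lie inside segment i on *both* sequences, divided by the number
#' of columns where *either* does. `method = "coverage"` instead reports the
#' fraction of sequence A's segment-i residues whose aligned partner lies in
#' segment i of B. The overall score is the mean over segments.
#'
#' @param aln an [AlignedPair-class].
#' @param tmA,tmB TM segments of sequences A and B: [IRanges::IRanges] (or
#'   2-column start/end matrices), 1-based inclusive on the ungapped
#'   sequences, equal segment counts.
#' @param method `"jaccard"` (default) or `"coverage"`.
#' @return A [ConsistencyScore-class].
#' @examples
#' fx <- generateAlignmentFixture(10, 10, cbind(3, 6), distortion = 2)
#' tmConsistencyScore(fx$aln, fx$tmA, fx$tmB)
#' @export
tmConsistencyScore <- function(aln, tmA, tmB,
                               method = c("jaccard", "coverage")) {
  method <- match.arg(method)
  tmA <- .asIRanges(tmA)
  tmB <- .asIRanges(tmB)
  if (length(tmA) != length(tmB))
    stop("segment counts differ between the two annotations")
  if (length(tmA) == 0L) stop("at least one TM segment required")
  cols <- mapAlignmentColumns(aln)
  lenA <- sum(!is.na(cols$posA)); lenB <- sum(!is.na(cols$posB))
  if (max(IRanges::end(tmA)) > lenA || max(IRanges::end(tmB)) > lenB)
    stop("TM intervals exceed the ungapped sequence length")
  per <- vapply(seq_along(tmA), function(i) {
    inA <- !is.na(cols$posA) & cols$posA >= IRanges::start(tmA)[i] &
      cols$posA <= IRanges::end(tmA)[i]
    inB <- !is.na(cols$posB) & cols$posB >= IRanges::start(tmB)[i] &
      cols$posB <= IRanges::end(tmB)[i]
    if (method == "jaccard") {
      u <- sum(inA | inB)
      if (u == 0L) 0 else sum(inA & inB) / u
    } else {
      sum(inA & inB) / sum(inA)
    }
  }, numeric(1))
  new("ConsistencyScore", perSegment = per, overall = mean(per),
      method = method)
}

#' Rank candidate alignments by TM consistency
#'
#' Scores each alignment with [tmConsistencyScore()] and orders them by
#' descending overall score; exact ties are broken by the lexicographic
#' order of `sourceLabel`, so the ranking is deterministic.
#'
#' @param alns list of [AlignedPair-class] objects (>= 1).
#' @param tmA,tmB per-alignment TM annotations: either a single annotation
#'   shared by all alignments or a list, one per alignment.
#' @param method passed to [tmConsistencyScore()].
#' @return data.frame ordered best-first with columns `rank`,
#'   `sourceLabel`, `overall`, and the list-column `perSegment`.
#' @export
rankAlignments <- function(alns, tmA, tmB, method = "jaccard") {
  if (length(alns) < 1L) stop("at least one alignment required")
  asList <- function(x) if (is.list(x) && !methods::is(x, "IRanges"))
    x else rep(list(x), length(alns))
  tmA <- asList(tmA); tmB <- asList(tmB)
  scores <- lapply(seq_along(alns), function(i)
    tmConsistencyScore(alns[[i]], tmA[[i]], tmB[[i]], method = method))
  lab <- vapply(alns, function(a) a@sourceLabel, character(1))
  ov <- vapply(scores, overallScore, numeric(1))
  o <- order(-ov, lab)
  out <- data.frame(rank = seq_along(alns), sourceLabel = lab[o],
                    overall = ov[o])
  out$perSegment <- lapply(scores[o], perSegment)
  out
}
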