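## Docking-pose classification, contact residues, and concordance ranking
## against mutagenesis data.

#' Cluster docking poses into binding-site types
#'
#' Single-linkage agglomeration of pose centroids (mean ligand heavy-atom
#' position per pose) on Euclidean distance, cut at `cutoff`. Binding-site
#' type ids are assigned in order of each cluster's best (lowest-rank,
#' i.e. energetically most favorable) member, so type 1 always contains
#' pose #1.
#'
#' @param poses a [DockingPoseSet-class].
#' @param cutoff single-linkage distance cutoff in Angstrom (default 5):
#'   poses whose centroids chain together within this distance share a
#'   type.
#' @return A [PoseClustering-class].
#' @examples
#' centers <- rbind(c(0, 0, 0), c(40, 0, 0), c(0, 40, 0))
#' ps <- generatePoseFixture(poseSimConfig(centers, c(4, 4, 2)))
#' clusterPoses(ps)
#' @export
clusterPoses <- function(poses, cutoff = 5) {
  stopifnot(is(poses, "DockingPoseSet"))
  .assertScalar(cutoff, "cutoff", 0, strict_lower = TRUE)
  cent <- t(vapply(poseCoords(poses), colMeans, numeric(3)))
  n <- nPoses(poses)
  grp <- if (n == 1L) 1L else {
    hc <- hclust(dist(cent), method = "single")
    cutree(hc, h = cutoff)
  }
  # renumber types by best (lowest) member rank
  bestRank <- vapply(split(poseRanks(poses), grp), min, numeric(1))
  newId <- match(grp, as.integer(names(sort(bestRank))))
  centroids <- t(vapply(seq_len(max(newId)), function(k)
    colMeans(cent[newId == k, , drop = FALSE]), numeric(3)))
  new("PoseClustering",
      assignments = setNames(as.integer(newId),
                             as.character(poseRanks(poses))),
      centroids = centroids, cutoff = cutoff)
}

#' Contact residues of a ligand pose
#'
#' A receptor residue is in contact when the minimum Euclidean distance
#' between any of its heavy atoms and any ligand heavy atom is at most
#' `cutoff` (boundary inclusive). This distance rule stands in for
#' buried-surface interface analysis; the 4 Angstrom default spans the
#' hydrogen-bond and CH-pi range that dominates protein-carbohydrate
#' recognition.
#'
#' @param ligandCoords numeric nAtoms x 3 matrix of ligand heavy-atom
#'   coordinates (Angstrom), or a [DockingPoseSet-class] together with
#'   `pose` selecting one rank.
#' @param receptor receptor structure as a data.frame with columns `chain`,
#'   `resno` (author numbering, 1-based), `resid`, `x`, `y`, `z` -- one row
#'   per heavy atom (see [readReceptorPDB()]).
#' @param cutoff contact distance cutoff in Angstrom, default 4.
#' @param pose pose rank to extract when `ligandCoords` is a pose set.
#' @return A [ContactSet-class]; its `residues` table reports the
#'   per-residue minimum heavy-atom distance.
#' @examples
#' rec <- data.frame(chain = "A", resno = 1:3, resid = c("ASP", "VAL", "LEU"),
#'                   x = c(3, 4, 4.1), y = 0, z = 0)
#' ligandContacts(matrix(0, 1, 3), rec, cutoff = 4)
#' @export
ligandContacts <- function(ligandCoords, receptor, cutoff = 4, pose = NULL) {
  if (is(ligandCoords, "DockingPoseSet")) {
    if (is.null(pose)) stop("select a pose rank with 'pose'")
    ligandCoords <- poseCoords(ligandCoords)[[match(pose,
                                                    poseRanks(ligandCoords))]]
  }
  ligandCoords <- as.matrix(ligandCoords)
  .assertScalar(cutoff, "cutoff", 0, strict_lower = TRUE)
  need <- c("chain", "resno", "resid", "x", "y", "z")
  if (!is.data.frame(receptor) || !all(need %in% names(receptor)) ||
      nrow(receptor) == 0L)
    stop("receptor must be a nonempty data.frame with columns ",
         paste(need, collapse = ", "))
  if (nrow(ligandCoords) == 0L) stop("ligand has no atoms")
  rxyz <- as.matrix(receptor[, c("x", "y", "z")])
  # nRec x nLig squared distances via the expansion |a-b|^2 = |a|^2+|b|^2-2ab
  d2 <- outer(rowSums(rxyz^2), rowSums(ligandCoords^2), `+`) -
    2 * rxyz %*% t(ligandCoords)
  minAtom <- sqrt(pmax(apply(d2, 1, min), 0))
  key <- paste(receptor$chain, receptor$resno, sep = "|")
  minRes <- vapply(split(minAtom, key), min, numeric(1))
  first <- !duplicated(key)
  tab <- data.frame(chain = receptor$chain[first],
                    resno = receptor$resno[first],
                    resid = receptor$resid[first],
                    minDist = unname(minRes[key[first]]))
  tab <- tab[tab$minDist <= cutoff, , drop = FALSE]
  tab <- tab[order(tab$chain, tab$resno), , drop = FALSE]
  rownames(tab) <- NULL
  new("ContactSet", residues = tab, cutoff = cutoff)
}

#' Residues whose mutation abolishes the ligand response
#'
#' Selects from a mutagenesis table the residues whose relative response
#' (fraction of wild type) falls strictly below `threshold`. The default
#' 0.01 corresponds to the "response essentially lost" class; a threshold
#' of 0.5 additionally admits the partially impaired (1--50%) class.
#'
#' @param table data.frame with columns `residue_number`, `residue_name`
#'   (one-letter or three-letter, free text) and `relative_response`
#'   (>= 0, fraction of wild type).
#' @param threshold response fraction in (0, 1); default 0.01.
#' @return Integer vector of residue numbers, named by residue label
#'   (e.g. `"D99"`), sorted.
#' @examples
#' tab <- data.frame(residue_number = c(99, 100),
#'                   residue_name = c("D", "A"),
#'                   relative_response = c(0.005, 0.9))
#' criticalResidues(tab)
#' @export
criticalResidues <- function(table, threshold = 0.01) {
  need <- c("residue_number", "relative_response")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("table needs columns residue_number, relative_response")
  .assertScalar(threshold, "threshold", 0, 1, strict_lower = TRUE)
  if (threshold >= 1) stop("'threshold' must be < 1")
  if (any(table$relative_response < 0))
    stop("relative responses must be >= 0")
  sel <- table$relative_response < threshold
  res <- sort(as.integer(table$residue_number[sel]))
  nm <- if (!is.null(table$residue_name))
    paste0(table$residue_name, table$residue_number) else
      as.character(table$residue_number)
  setNames(res, nm[sel][order(as.integer(table$residue_number[sel]))])
}

#' Rank binding-site types by coverage of critical residues
#'
#' For each binding-site type, the contact sets of its member poses are
#' unioned and the coverage computed as the fraction of critical residues
#' (mutation abolishes the response) found in that union. Types are
#' returned in descending coverage order; a coverage of 1 reproduces the
#' "every response-critical residue lies in this site" criterion that
#' singles out the true ligand-binding site.
#'
#' @param clustering a [PoseClustering-class].
#' @param contactSets list of [ContactSet-class], named (or ordered) by pose
#'   rank, one per pose.
#' @param critical integer vector of critical residue numbers (nonempty;
#'   see [criticalResidues()]).
#' @return data.frame ordered best-first: `typeId`, `coverage`,
#'   `nContactResidues`, `memberRanks` (list-column).
#' @export
rankBindingTypes <- function(clustering, contactSets, critical) {
  stopifnot(is(clustering, "PoseClustering"))
  if (length(critical) == 0L)
    stop("coverage is undefined for an empty critical-residue set")
  asg <- typeAssignments(clustering)
  if (length(contactSets) != length(asg))
    stop("one contact set per pose required")
  if (is.null(names(contactSets))) names(contactSets) <- names(asg)
  critical <- unique(as.integer(critical))
  rows <- lapply(seq_len(nTypes(clustering)), function(k) {
    ranks <- names(asg)[asg == k]
    un <- unique(unlist(lapply(contactSets[ranks], function(cs)
      contactResidues(cs)$resno)))
    data.frame(typeId = k,
               coverage = length(intersect(un, critical)) / length(critical),
               nContactResidues = length(un))
  })
  out <- do.call(rbind, rows)
  o <- order(-out$coverage, out$typeId)
  out <- out[o, , drop = FALSE]
  out$memberRanks <- lapply(out$typeId, function(k)
    sort(as.integer(names(asg)[asg == k])))
  rownames(out) <- NULL
  out
}
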