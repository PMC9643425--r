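## Readers and writers for the pipeline's plain-text exchange formats.

#' Read and write bleach traces as TSV
#'
#' Long format with columns `spot_id`, `time_s`, `intensity_au`; one block
#' of uniformly spaced samples per spot.
#'
#' @param path file path.
#' @param traces list of [BleachTrace-class] (named or auto-numbered).
#' @return `readTraceTSV()`: a named list of [BleachTrace-class];
#'   `writeTraceTSV()`: the path, invisibly.
#' @name traceIO
NULL

#' @rdname traceIO
#' @export
writeTraceTSV <- function(traces, path) {
  if (is(traces, "BleachTrace")) traces <- list(traces)
  if (is.null(names(traces)))
    names(traces) <- sprintf("spot%04d", seq_along(traces))
  tab <- do.call(rbind, lapply(names(traces), function(id) {
    tr <- traces[[id]]
    data.frame(spot_id = id,
               time_s = (seq_len(nFrames(tr)) - 1) * frameInterval(tr) / 1000,
               intensity_au = intensities(tr))
  }))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname traceIO
#' @export
readTraceTSV <- function(path) {
  tab <- read.delim(path)
  need <- c("spot_id", "time_s", "intensity_au")
  if (!all(need %in% names(tab)))
    stop("trace TSV needs columns ", paste(need, collapse = ", "))
  lapply(split(tab, tab$spot_id), function(d) {
    d <- d[order(d$time_s), ]
    dt <- diff(d$time_s)
    BleachTrace(d$intensity_au, frameInterval = 1000 * median(dt))
  })
}

#' Read and write step-count histograms as TSV
#'
#' Columns `steps`, `count`.
#'
#' @param hist a [StepCountHistogram-class].
#' @param path file path.
#' @return `readStepHistogram()`: a [StepCountHistogram-class];
#'   `writeStepHistogram()`: the path, invisibly.
#' @name histIO
NULL

#' @rdname histIO
#' @export
writeStepHistogram <- function(hist, path) {
  stopifnot(is(hist, "StepCountHistogram"))
  cnt <- stepCounts(hist)
  write.table(data.frame(steps = as.integer(names(cnt)), count = cnt),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname histIO
#' @export
readStepHistogram <- function(path) {
  tab <- read.delim(path)
  if (!all(c("steps", "count") %in% names(tab)))
    stop("histogram TSV needs columns steps, count")
  StepCountHistogram(setNames(tab$count, tab$steps))
}

#' Read and write reversal-potential records as TSV
#'
#' Columns `cell_id`, `erev_na_mV`, `erev_k_mV`, `junction_na_mV`,
#' `junction_k_mV` (junctions optional on read, defaulting to 0).
#'
#' @param records data.frame of records.
#' @param path file path.
#' @return `readReversalRecords()`: a validated data.frame;
#'   `writeReversalRecords()`: the path, invisibly.
#' @name recordIO
NULL

#' @rdname recordIO
#' @export
writeReversalRecords <- function(records, path) {
  records <- .checkRecords(records)
  write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname recordIO
#' @export
readReversalRecords <- function(path) {
  tab <- read.delim(path)
  bad <- which(!stats::complete.cases(tab[, intersect(
    c("erev_na_mV", "erev_k_mV"), names(tab)), drop = FALSE]))
  if (length(bad))
    stop("malformed reversal record at line ", bad[1] + 1L, " of ", path)
  .checkRecords(tab)
}

#' Read a receptor structure from PDB
#'
#' Parses a PDB file (via bio3d) and returns the heavy-atom table used by
#' [ligandContacts()]: hydrogens and non-protein records are dropped, and
#' residues keep the author numbering of the file, matching mutagenesis
#' labels such as D99.
#'
#' @param path PDB file path.
#' @return data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @export
readReceptorPDB <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM" & !grepl("^H", pdb$atom$elety), ]
  if (nrow(at) == 0L) stop("no protein heavy atoms found in ", path)
  data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
             elety = at$elety, x = at$x, y = at$y, z = at$z)
}

#' Read and write docking pose sets
#'
#' Poses travel as multi-model PDB (one `MODEL`/`ENDMDL` block per pose,
#' HETATM ligand records) plus a sidecar TSV with columns `rank`,
#' `affinity_kcal_mol` and optionally `true_cluster` (for synthetic
#' fixtures).
#'
#' @param poses a [DockingPoseSet-class].
#' @param pdbPath multi-model PDB path.
#' @param tsvPath sidecar TSV path; defaults to `pdbPath` with a `.tsv`
#'   extension.
#' @return `readPoseSet()`: a [DockingPoseSet-class]; `writePoseSet()`: the
#'   PDB path, invisibly.
#' @name poseIO
NULL

#' @rdname poseIO
#' @export
writePoseSet <- function(poses, pdbPath, tsvPath = sub("\\.pdb$", ".tsv",
                                                       pdbPath)) {
  stopifnot(is(poses, "DockingPoseSet"))
  con <- file(pdbPath, "w")
  on.exit(close(con))
  for (i in seq_len(nPoses(poses))) {
    xyz <- poseCoords(poses)[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf("REMARK VINA RESULT: %8.3f", affinities(poses)[i]),
               con)
    writeLines(sprintf(
      "HETATM%5d  C%-2d LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(xyz)), seq_len(nrow(xyz)), xyz[, 1], xyz[, 2], xyz[, 3]),
      con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  tab <- data.frame(rank = poseRanks(poses),
                    affinity_kcal_mol = affinities(poses),
                    true_cluster = trueClusters(poses))
  write.table(tab, tsvPath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(pdbPath)
}

#' @rdname poseIO
#' @export
readPoseSet <- function(pdbPath, tsvPath = sub("\\.pdb$", ".tsv", pdbPath)) {
  pdb <- bio3d::read.pdb(pdbPath, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  coords <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  rank <- seq_along(coords)
  affinity <- rep(NA_real_, length(coords))
  trueCluster <- rep(NA_integer_, length(coords))
  if (file.exists(tsvPath)) {
    tab <- read.delim(tsvPath)
    stopifnot(nrow(tab) == length(coords))
    rank <- tab$rank
    affinity <- tab$affinity_kcal_mol
    if (!is.null(tab$true_cluster)) trueCluster <- as.integer(tab$true_cluster)
  }
  dockingPoseSet(coords, rank = rank, affinity = affinity,
                 trueCluster = trueCluster)
}

#' Read an aligned FASTA pair
#'
#' Reads a two-record aligned FASTA (gaps as `-`) into an
#' [AlignedPair-class]; record order gives sequences A and B.
#'
#' @param path aligned FASTA path.
#' @param sourceLabel label for the alignment; defaults to the file name.
#' @return An [AlignedPair-class].
#' @export
readAlignedFasta <- function(path, sourceLabel = basename(path)) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) != 2L)
    stop("expected exactly 2 records in ", path, ", found ", length(ss))
  alignedPair(as.character(ss[[1]]), as.character(ss[[2]]),
              sourceLabel = sourceLabel)
}

#' Read and write TM-segment annotations as TSV
#'
#' Columns `seq_id`, `segment_index`, `start`, `end` (1-based inclusive on
#' the ungapped sequence).
#'
#' @param path file path.
#' @param segments an [IRanges::IRanges] of TM intervals.
#' @param seqId sequence identifier to write.
#' @return `readTMSegments()`: an [IRanges::IRanges] (rows for `seqId` when
#'   given, else all); `writeTMSegments()`: the path, invisibly.
#' @name tmIO
NULL

#' @rdname tmIO
#' @export
writeTMSegments <- function(segments, path, seqId = "seq") {
  segments <- .asIRanges(segments)
  write.table(data.frame(seq_id = seqId,
                         segment_index = seq_along(segments),
                         start = IRanges::start(segments),
                         end = IRanges::end(segments)),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tmIO
#' @export
readTMSegments <- function(path, seqId = NULL) {
  tab <- read.delim(path)
  need <- c("segment_index", "start", "end")
  if (!all(need %in% names(tab)))
    stop("TM TSV needs columns ", paste(need, collapse = ", "))
  if (!is.null(seqId)) tab <- tab[tab$seq_id == seqId, , drop = FALSE]
  tab <- tab[order(tab$segment_index), , drop = FALSE]
  IRanges::IRanges(start = tab$start, end = tab$end)
}

#' Read a mutagenesis response table
#'
#' TSV with columns `residue_number`, `residue_name`, `relative_response`
#' (fraction of the wild-type response amplitude).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readMutagenesisTable <- function(path) {
  tab <- read.delim(path)
  need <- c("residue_number", "relative_response")
  if (!all(need %in% names(tab)))
    stop("mutagenesis TSV needs columns ", paste(need, collapse = ", "))
  tab
}
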