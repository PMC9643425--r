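## Synthetic-data generators: every input the pipeline consumes, with known
## ground truth.

#' Simulation configuration objects
#'
#' Validated parameter bundles for the synthetic-data generators.
#'
#' `traceSimConfig()` describes stepwise-photobleaching traces: a spot
#' carries `nSubunits` subunits, each tagged with a GFP that is fluorescent
#' with probability `pFluor`; fluorescent tags bleach at i.i.d. exponential
#' times and each bleach event drops the intensity by `stepAmplitude`.
#' Defaults: 113 ms/frame acquisition, 8 s mean bleach time, 60 s recording,
#' unit step amplitude, noise SD 0.2 (SNR 5).
#'
#' `electroSimConfig()` describes ion-substitution reversal-potential pairs
#' under a chosen true permeability ratio P_K/P_Na: the noiseless shift is
#' `dErev = (RT/F) * ln(trueRatio * kOut / naOut)` (mV), and independent
#' Gaussian noise of SD `erevNoiseSd` perturbs each of Erev(Na+), Erev(K+).
#' Defaults mirror the 98 mM single-cation bath pair and 22 C recordings.
#'
#' `poseSimConfig()` describes spatially clustered docking-pose fixtures:
#' pose centroids scatter isotropically (SD `spreadSd`) around their cluster
#' center, and each pose is a rigid cloud of `nLigandAtoms` atoms.
#'
#' @param nSubunits integer subunit count (>= 1).
#' @param pFluor probability in \[0, 1\] that one subunit's tag fluoresces.
#' @param frameInterval frame interval, ms (> 0).
#' @param meanBleachTime mean exponential bleach time per fluorophore, s.
#' @param stepAmplitude fluorescence drop per bleach event, a.u. (> 0).
#' @param noiseSd per-frame Gaussian noise SD, a.u.
#' @param duration recorded duration, s (> 0).
#' @param trueRatio true P_K/P_Na (> 0, dimensionless).
#' @param naOut,kOut outer bath concentrations, mM (> 0).
#' @param temperature absolute temperature, K.
#' @param erevNoiseSd measurement noise SD on each reversal potential, mV.
#' @param nCells number of oocytes (records) per simulated group.
#' @param clusterCenters numeric matrix (K x 3) of cluster centers, Angstrom.
#' @param clusterSizes integer vector of poses per cluster (length K).
#' @param spreadSd isotropic spread of pose centroids around their center, A.
#' @param nLigandAtoms heavy atoms per ligand pose.
#' @param seed integer seed; every generator is deterministic given its seed.
#' @return A named list of validated parameters with class
#'   `"TraceSimConfig"`, `"ElectroSimConfig"` or `"PoseSimConfig"`.
#' @examples
#' traceSimConfig(nSubunits = 4, pFluor = 0.776, seed = 1)
#' @name simConfigs
NULL

#' @rdname simConfigs
#' @export
traceSimConfig <- function(nSubunits = 4L, pFluor = 0.776,
                           frameInterval = 113, meanBleachTime = 8,
                           stepAmplitude = 1, noiseSd = 0.2, duration = 60,
                           seed = 1L) {
  nSubunits <- .assertCount(nSubunits, "nSubunits")
  .assertScalar(pFluor, "pFluor", 0, 1)
  .assertScalar(frameInterval, "frameInterval", 0, strict_lower = TRUE)
  .assertScalar(meanBleachTime, "meanBleachTime", 0, strict_lower = TRUE)
  .assertScalar(stepAmplitude, "stepAmplitude", 0, strict_lower = TRUE)
  .assertScalar(noiseSd, "noiseSd", 0)
  .assertScalar(duration, "duration", 0, strict_lower = TRUE)
  structure(list(nSubunits = nSubunits, pFluor = pFluor,
                 frameInterval = frameInterval,
                 meanBleachTime = meanBleachTime,
                 stepAmplitude = stepAmplitude, noiseSd = noiseSd,
                 duration = duration, seed = as.integer(seed)),
            class = "TraceSimConfig")
}

#' @rdname simConfigs
#' @export
electroSimConfig <- function(trueRatio = 1, naOut = 98, kOut = 98,
                             temperature = 295.15, erevNoiseSd = 2,
                             nCells = 15L, seed = 1L) {
  .assertScalar(trueRatio, "trueRatio", 0, strict_lower = TRUE)
  .assertScalar(naOut, "naOut", 0, strict_lower = TRUE)
  .assertScalar(kOut, "kOut", 0, strict_lower = TRUE)
  .assertScalar(temperature, "temperature", 0, strict_lower = TRUE)
  .assertScalar(erevNoiseSd, "erevNoiseSd", 0)
  nCells <- .assertCount(nCells, "nCells")
  structure(list(trueRatio = trueRatio, naOut = naOut, kOut = kOut,
                 temperature = temperature, erevNoiseSd = erevNoiseSd,
                 nCells = nCells, seed = as.integer(seed)),
            class = "ElectroSimConfig")
}

#' @rdname simConfigs
#' @export
poseSimConfig <- function(clusterCenters, clusterSizes, spreadSd = 0.5,
                          nLigandAtoms = 12L, seed = 1L) {
  clusterCenters <- as.matrix(clusterCenters)
  if (ncol(clusterCenters) != 3L)
    stop("'clusterCenters' must be a K x 3 matrix")
  if (nrow(clusterCenters) != length(clusterSizes))
    stop("one cluster size per cluster center required")
  if (any(clusterSizes < 1L)) stop("cluster sizes must be >= 1")
  .assertScalar(spreadSd, "spreadSd", 0)
  nLigandAtoms <- .assertCount(nLigandAtoms, "nLigandAtoms")
  structure(list(clusterCenters = clusterCenters,
                 clusterSizes = as.integer(clusterSizes),
                 spreadSd = spreadSd, nLigandAtoms = nLigandAtoms,
                 seed = as.integer(seed)),
            class = "PoseSimConfig")
}

#' Simulate a photobleaching step-count histogram
#'
#' Draws, for each of `nSpots` spots, the number of fluorescent subunits
#' from the binomial law Bin(`nSubunits`, `pFluor`) conditioned on at least
#' one fluorescent subunit -- a spot with zero fluorescent tags is dark and
#' can never be selected for step counting, so the observable support starts
#' at 1.
#'
#' @param nSpots number of observed spots (> 0).
#' @param nSubunits subunit count of the generating oligomer (>= 1).
#' @param pFluor probability a subunit's tag is fluorescent, in (0, 1].
#' @param seed integer seed.
#' @return A [StepCountHistogram-class] with keys `1..nSubunits` (zero
#'   counts kept) summing to `nSpots`.
#' @examples
#' simulateStepCounts(569, 4, 0.776, seed = 1)
#' @export
simulateStepCounts <- function(nSpots, nSubunits, pFluor, seed = 1L) {
  nSpots <- .assertCount(nSpots, "nSpots")
  nSubunits <- .assertCount(nSubunits, "nSubunits")
  .assertScalar(pFluor, "pFluor", 0, 1)
  if (pFluor == 0)
    stop("pFluor = 0 leaves every spot dark; no observable histogram")
  pmf <- conditionalBinomialPmf(nSubunits, pFluor)
  k <- withSeed(seed,
    sample.int(nSubunits, nSpots, replace = TRUE, prob = pmf))
  StepCountHistogram(setNames(tabulate(k, nbins = nSubunits),
                              seq_len(nSubunits)))
}

#' Simulate one stepwise-photobleaching trace
#'
#' Constructs the piecewise-constant ground truth -- `nFluor` fluorophores
#' at `stepAmplitude` each, dropping one unit at each of `nFluor` i.i.d.
#' exponential bleach times -- sampled at the frame interval, plus i.i.d.
#' Gaussian noise. Frame `j` samples the level at time
#' `(j - 1) * frameInterval` (instantaneous sampling; no exposure
#' integration). Bleach times beyond the recorded duration are not
#' observable and are excluded from the returned ground truth.
#'
#' @param config a [traceSimConfig()] object.
#' @param nFluor number of initially fluorescent subunits,
#'   `0 <= nFluor <= nSubunits`.
#' @param seed integer seed; defaults to `config$seed`.
#' @return A [BleachTrace-class] carrying its ground-truth bleach times.
#' @examples
#' tr <- simulateBleachTrace(traceSimConfig(noiseSd = 0), nFluor = 3)
#' length(groundTruthSteps(tr))
#' @export
simulateBleachTrace <- function(config, nFluor, seed = config$seed) {
  stopifnot(inherits(config, "TraceSimConfig"))
  nFluor <- .assertCount(nFluor, "nFluor", min = 0L)
  if (nFluor > config$nSubunits)
    stop("nFluor exceeds nSubunits")
  dt <- config$frameInterval / 1000
  tframe <- seq(0, config$duration, by = dt)
  withSeed(seed, {
    btimes <- sort(rexp(nFluor, rate = 1 / config$meanBleachTime))
    level <- nFluor - findInterval(tframe, btimes)
    noise <- if (config$noiseSd > 0)
      rnorm(length(tframe), 0, config$noiseSd) else 0
    BleachTrace(level * config$stepAmplitude + noise,
                frameInterval = config$frameInterval,
                groundTruthSteps = btimes[btimes <= max(tframe)])
  })
}

#' Simulate a set of traces from an oligomer population
#'
#' Draws each spot's fluorophore number from the conditional binomial law
#' (at least one fluorescent tag) and simulates one trace per spot.
#'
#' @inheritParams simulateBleachTrace
#' @param nSpots number of traces.
#' @return A list of [BleachTrace-class] objects.
#' @export
simulateTraces <- function(config, nSpots, seed = config$seed) {
  stopifnot(inherits(config, "TraceSimConfig"))
  nSpots <- .assertCount(nSpots, "nSpots")
  pmf <- conditionalBinomialPmf(config$nSubunits, config$pFluor)
  withSeed(seed, {
    nf <- sample.int(config$nSubunits, nSpots, replace = TRUE, prob = pmf)
    tseeds <- sample.int(.Machine$integer.max, nSpots)
    lapply(seq_len(nSpots), function(i)
      simulateBleachTrace(config, nf[i], seed = tseeds[i]))
  })
}

#' Simulate ion-substitution reversal-potential records
#'
#' Each simulated oocyte yields a reversal potential in the Na+ bath and in
#' the K+ bath. The noiseless shift `dErev = Erev(Na+) - Erev(K+)` satisfies
#' the inverted Goldman-Hodgkin-Katz relation
#' `dErev = (RT/F) * ln(trueRatio * kOut / naOut)`, so that
#' [permeabilityRatio()] applied to a noiseless record returns `trueRatio`
#' exactly. Gaussian noise of SD `erevNoiseSd` is added independently to
#' each bath's measurement; the supplied junction potentials are *added* to
#' the stored measurements so that [correctJunction()] recovers them.
#'
#' @param config an [electroSimConfig()] object.
#' @param junctionNa,junctionK known junction potentials (mV) baked into the
#'   simulated measurements; default 0.
#' @param erevKBase baseline K+-bath reversal potential (mV) about which
#'   records are centered.
#' @param seed integer seed; defaults to `config$seed`.
#' @return A data.frame of reversal-potential records with columns
#'   `cell_id`, `erev_na_mV`, `erev_k_mV`, `junction_na_mV`,
#'   `junction_k_mV`.
#' @examples
#' simulateReversalPairs(electroSimConfig(trueRatio = 2, erevNoiseSd = 0,
#'                                        nCells = 3))
#' @export
simulateReversalPairs <- function(config, junctionNa = 0, junctionK = 0,
                                  erevKBase = -20, seed = config$seed) {
  stopifnot(inherits(config, "ElectroSimConfig"))
  rtF <- 1000 * 8.314 * config$temperature / 96485   # mV
  dErev <- rtF * log(config$trueRatio * config$kOut / config$naOut)
  withSeed(seed, {
    noiseK <- if (config$erevNoiseSd > 0)
      rnorm(config$nCells, 0, config$erevNoiseSd) else numeric(config$nCells)
    noiseNa <- if (config$erevNoiseSd > 0)
      rnorm(config$nCells, 0, config$erevNoiseSd) else numeric(config$nCells)
    data.frame(cell_id = sprintf("cell%02d", seq_len(config$nCells)),
               erev_na_mV = erevKBase + dErev + noiseNa + junctionNa,
               erev_k_mV = erevKBase + noiseK + junctionK,
               junction_na_mV = junctionNa,
               junction_k_mV = junctionK)
  })
}

#' Generate a planted-partition docking-pose fixture
#'
#' Poses are laid down cluster by cluster: each pose's centroid is its
#' cluster center plus isotropic Gaussian displacement (`spreadSd`), and the
#' ligand atom cloud is a fixed rigid arrangement shared by all poses,
#' translated to the centroid. Pose ranks run #1..#N in generation order and
#' affinities increase (become less favorable) with rank, mirroring
#' energy-ordered docking output. Ground-truth cluster labels are retained.
#'
#' @param config a [poseSimConfig()] object.
#' @param seed integer seed; defaults to `config$seed`.
#' @return A [DockingPoseSet-class] with planted `trueClusters()` labels.
#' @examples
#' centers <- rbind(c(0, 0, 0), c(40, 0, 0), c(0, 40, 0))
#' ps <- generatePoseFixture(poseSimConfig(centers, c(4, 4, 2)))
#' nPoses(ps)
#' @export
generatePoseFixture <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "PoseSimConfig"))
  nPose <- sum(config$clusterSizes)
  labels <- rep(seq_along(config$clusterSizes), config$clusterSizes)
  withSeed(seed, {
    # one rigid atom cloud shared by all poses (zero-mean)
    cloud <- matrix(rnorm(config$nLigandAtoms * 3, sd = 1.2), ncol = 3)
    cloud <- sweep(cloud, 2, colMeans(cloud))
    coords <- lapply(seq_len(nPose), function(i) {
      centroid <- config$clusterCenters[labels[i], ] +
        if (config$spreadSd > 0) rnorm(3, 0, config$spreadSd) else 0
      sweep(cloud, 2, centroid, `+`)
    })
    affinity <- -8 + 0.3 * (seq_len(nPose) - 1) +
      cumsum(c(0, runif(nPose - 1, 0, 0.05)))
    dockingPoseSet(coords, rank = seq_len(nPose), affinity = affinity,
                   trueCluster = labels)
  })
}

#' Generate a toy alignment fixture with known TM overlap
#'
#' Builds two random protein sequences, an identity (column-for-column)
#' alignment between them, and paired TM-segment annotations whose
#' column-overlap structure is known exactly: sequence B's TM intervals are
#' those of A shifted by `distortion` residues, so each segment pair of TM
#' length L overlaps in `L - distortion` columns out of `L + distortion`
#' (Jaccard `(L - d) / (L + d)`, zero once `d >= L`).
#'
#' @param lenA,lenB sequence lengths; trailing columns of the longer
#'   sequence are aligned to gaps.
#' @param tmLayout an [IRanges::IRanges] (or 2-column start/end matrix) of
#'   TM intervals on sequence A, 1-based inclusive.
#' @param distortion nonnegative integer shift applied to B's intervals.
#' @param seed integer seed for the random residues.
#' @return A list with elements `aln` ([AlignedPair-class]), `tmA` and `tmB`
#'   ([IRanges::IRanges]).
#' @examples
#' fx <- generateAlignmentFixture(10, 10, cbind(3, 6), distortion = 2)
#' overallScore(tmConsistencyScore(fx$aln, fx$tmA, fx$tmB))  # 2/6
#' @export
generateAlignmentFixture <- function(lenA, lenB, tmLayout, distortion = 0L,
                                     seed = 1L) {
  lenA <- .assertCount(lenA, "lenA")
  lenB <- .assertCount(lenB, "lenB")
  distortion <- .assertCount(distortion, "distortion", min = 0L)
  tmA <- .asIRanges(tmLayout)
  if (length(tmA) == 0L) stop("at least one TM interval required")
  if (min(IRanges::start(tmA)) < 1L || max(IRanges::end(tmA)) > lenA)
    stop("TM intervals out of sequence A bounds")
  tmB <- IRanges::shift(tmA, distortion)
  if (max(IRanges::end(tmB)) > lenB)
    stop("distorted TM intervals out of sequence B bounds")
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  ncol_ <- max(lenA, lenB)
  withSeed(seed, {
    sa <- sample(aa, lenA, replace = TRUE)
    sb <- sample(aa, lenB, replace = TRUE)
    seqA <- paste(c(sa, rep("-", ncol_ - lenA)), collapse = "")
    seqB <- paste(c(sb, rep("-", ncol_ - lenB)), collapse = "")
    list(aln = alignedPair(seqA, seqB,
                           sourceLabel = sprintf("toy-d%d", distortion)),
         tmA = tmA, tmB = tmB)
  })
}

.asIRanges <- function(x) {
  if (methods::is(x, "IRanges")) return(x)
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("TM intervals must be an IRanges or 2-column matrix")
  IRanges::IRanges(start = as.integer(x[, 1]), end = as.integer(x[, 2]))
}
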