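## Orchestration: shared run configuration and the three analysis drivers,
## each producing one machine-readable JSON report.

#' Shared run configuration
#'
#' Bundles the tunable parameters and input/output paths of the pipeline.
#' Values may come from a YAML or JSON file (`file`), with direct arguments
#' taking precedence over the file and the file over the defaults.
#'
#' @param seed integer seed used by any simulation step.
#' @param temperature bath temperature, K.
#' @param naOut,kOut outer bath concentrations, mM.
#' @param contactCutoff heavy-atom contact cutoff, Angstrom.
#' @param clusterCutoff pose-clustering single-linkage cutoff, Angstrom.
#' @param alpha significance level for model selection, in (0, 1).
#' @param candidates candidate subunit counts.
#' @param criticalThreshold relative-response threshold below which a
#'   mutated residue counts as critical.
#' @param sensitivity step-detection penalty multiplier.
#' @param paths named list of input/output file paths (free-form; the run
#'   drivers look up the keys they need).
#' @param file optional YAML (`.yml`/`.yaml`, requires the yaml package) or
#'   JSON config file.
#' @param ... further named overrides stored verbatim.
#' @return A named list with class `"RunConfig"`.
#' @export
runConfig <- function(seed = 1L, temperature = 295.15, naOut = 98, kOut = 98,
                      contactCutoff = 4, clusterCutoff = 5, alpha = 0.05,
                      candidates = c(4L, 5L, 6L), criticalThreshold = 0.01,
                      sensitivity = 2, paths = list(), file = NULL, ...) {
  cfg <- list(seed = as.integer(seed), temperature = temperature,
              naOut = naOut, kOut = kOut, contactCutoff = contactCutoff,
              clusterCutoff = clusterCutoff, alpha = alpha,
              candidates = as.integer(candidates),
              criticalThreshold = criticalThreshold,
              sensitivity = sensitivity, paths = paths, ...)
  if (!is.null(file)) {
    fromFile <- if (grepl("\\.ya?ml$", file)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the yaml package")
      yaml::read_yaml(file)
    } else jsonlite::read_json(file, simplifyVector = TRUE)
    given <- names(match.call(expand.dots = TRUE))  # CLI/caller > file
    for (k in setdiff(names(fromFile), given)) cfg[[k]] <- fromFile[[k]]
  }
  .assertScalar(cfg$alpha, "alpha", 0, 1, strict_lower = TRUE)
  .assertScalar(cfg$contactCutoff, "contactCutoff", 0, strict_lower = TRUE)
  .assertScalar(cfg$clusterCutoff, "clusterCutoff", 0, strict_lower = TRUE)
  structure(cfg, class = "RunConfig")
}

.provenance <- function(config) {
  cfg <- unclass(config)
  list(package = "grchannel",
       version = as.character(packageVersion("grchannel")),
       seed = config$seed, config = cfg)
}

.writeReport <- function(report, path) {
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    invisible(report)
  } else report
}

#' Run the stoichiometry analysis
#'
#' Reads (or simulates) a step-count histogram and performs chi-squared
#' model selection among the candidate oligomeric states. Inputs, in order
#' of precedence: `config$paths$hist` (a histogram TSV),
#' `config$paths$traces` (a trace TSV, counted with [countSteps()]), or --
#' if neither is present -- a simulated scenario of
#' `config$simSpots` spots (default 569) from an oligomer of
#' `config$simSubunits` (default 4) at `config$simPFluor` (default 0.776).
#'
#' @param config a [runConfig()].
#' @param out optional path for the JSON report.
#' @return The report, a list with elements `analysis`, `provenance`,
#'   `histogram`, `fits` (one row per candidate) and `retained`.
#' @export
runStoichiometry <- function(config = runConfig(), out = NULL) {
  if (length(config$candidates) == 0L)
    stop("configuration error: empty candidate list")
  src <- "simulated"
  if (!is.null(config$paths$hist)) {
    hist <- readStepHistogram(config$paths$hist)
    src <- config$paths$hist
  } else if (!is.null(config$paths$traces)) {
    hist <- countSteps(readTraceTSV(config$paths$traces),
                       sensitivity = config$sensitivity)
    src <- config$paths$traces
  } else {
    hist <- simulateStepCounts(
      nSpots = if (is.null(config$simSpots)) 569L else config$simSpots,
      nSubunits = if (is.null(config$simSubunits)) 4L else config$simSubunits,
      pFluor = if (is.null(config$simPFluor)) 0.776 else config$simPFluor,
      seed = config$seed)
  }
  fits <- selectOligomer(hist, candidates = config$candidates,
                         alpha = config$alpha)
  fitTab <- do.call(rbind, lapply(fits, function(f) data.frame(
    nSubunits = nSubunits(f), pHat = pHat(f), chisq = chisqStat(f),
    df = f@df, pValue = pValue(f), dfAlt = f@dfAlt,
    pValueAlt = f@pValueAlt, retained = isRetained(f),
    degenerate = f@degenerate)))
  report <- list(analysis = "stoichiometry", source = src,
                 provenance = .provenance(config),
                 histogram = as.list(stepCounts(hist)),
                 alpha = config$alpha, fits = fitTab,
                 retained = fitTab$nSubunits[which(fitTab$retained)])
  .writeReport(report, out)
}

#' Run the ion-selectivity analysis
#'
#' Computes junction-corrected GHK permeability ratios per record group and,
#' when both a wild-type and mutant groups are given, the WT-vs-mutant
#' Student's t statistics with Bonferroni correction over the mutant count.
#' Inputs: `config$paths$records` (single group) or `config$paths$wt` plus
#' `config$paths$mutants` (named vector/list of mutant record TSVs).
#'
#' @param config a [runConfig()].
#' @param out optional path for the JSON report.
#' @return The report: per-group `mean`, `sem`, `n`, and optionally a
#'   `comparisons` table of t/p/p_bonferroni per mutant.
#' @export
runSelectivity <- function(config = runConfig(), out = NULL) {
  cond <- ionCondition(config$naOut, config$kOut)
  consts <- physicalConstants(config$temperature)
  ratios <- function(path) {
    rec <- correctJunction(readReversalRecords(path))
    permeabilityRatio(rec, cond, consts)$ratio
  }
  groups <- list()
  if (!is.null(config$paths$records)) {
    groups[["all"]] <- ratios(config$paths$records)
  } else if (!is.null(config$paths$wt)) {
    groups[["WT"]] <- ratios(config$paths$wt)
    for (m in names(config$paths$mutants))
      groups[[m]] <- ratios(config$paths$mutants[[m]])
  } else stop("configuration error: no reversal-potential records given")
  summaries <- lapply(groups, summarizeGroup)
  report <- list(analysis = "selectivity", provenance = .provenance(config),
                 condition = cond, temperature_K = consts$temperature,
                 groups = summaries)
  mutants <- setdiff(names(groups), c("WT", "all"))
  if ("WT" %in% names(groups) && length(mutants)) {
    m <- length(mutants)
    cmp <- do.call(rbind, lapply(mutants, function(g) {
      cc <- compareGroups(groups$WT, groups[[g]], nComparisons = m)
      data.frame(mutant = g, t = cc$t, df = cc$df, pRaw = cc$pRaw,
                 pBonferroni = cc$pBonferroni,
                 significant = cc$pBonferroni < config$alpha)
    }))
    report$comparisons <- cmp
  }
  .writeReport(report, out)
}

#' Run the binding-pocket analysis
#'
#' Clusters the docking poses into binding-site types, maps contact
#' residues of every pose against the receptor, and -- when a mutagenesis
#' table is available -- ranks the types by coverage of the critical
#' residues. Without the table, clusters and contacts are still produced
#' and the ranking is skipped. Inputs: `config$paths$receptor` (PDB),
#' `config$paths$poses` (multi-model PDB + sidecar TSV),
#' `config$paths$mutagenesis` (TSV, optional).
#'
#' @param config a [runConfig()].
#' @param out optional path for the JSON report.
#' @return The report: `types`, `contacts` per pose, optional `ranking`,
#'   and `contactDefinition` carrying the distance-rule approximation flag.
#' @export
runPocket <- function(config = runConfig(), out = NULL) {
  if (is.null(config$paths$receptor) || is.null(config$paths$poses))
    stop("configuration error: receptor and poses paths are required")
  receptor <- readReceptorPDB(config$paths$receptor)
  poses <- readPoseSet(config$paths$poses)
  clustering <- clusterPoses(poses, cutoff = config$clusterCutoff)
  contactSets <- lapply(poseRanks(poses), function(r)
    ligandContacts(poses, receptor, cutoff = config$contactCutoff, pose = r))
  names(contactSets) <- as.character(poseRanks(poses))
  if (all(vapply(contactSets,
                 function(cs) nrow(contactResidues(cs)) == 0L, logical(1))))
    warning("no ligand pose contacts the receptor within ",
            config$contactCutoff,
            " A; the structures may not share a coordinate frame")
  report <- list(
    analysis = "binding-pocket", provenance = .provenance(config),
    contactDefinition = new("ContactSet", residues = data.frame(
      chain = character(), resno = integer(), resid = character(),
      minDist = numeric()), cutoff = config$contactCutoff)@definition,
    types = lapply(seq_len(nTypes(clustering)), function(k) list(
      typeId = k,
      memberRanks = sort(as.integer(names(typeAssignments(clustering))[
        typeAssignments(clustering) == k])),
      centroid = unname(typeCentroids(clustering)[k, ]))),
    contacts = lapply(contactSets, function(cs) contactResidues(cs)))
  if (!is.null(config$paths$mutagenesis)) {
    tab <- readMutagenesisTable(config$paths$mutagenesis)
    critical <- criticalResidues(tab, threshold = config$criticalThreshold)
    rk <- rankBindingTypes(clustering, contactSets, critical)
    report$criticalResidues <- as.list(setNames(critical, names(critical)))
    report$ranking <- rk[, c("typeId", "coverage", "nContactResidues")]
  } else {
    report$ranking <- NULL
    report$note <- "mutagenesis table absent; type ranking skipped"
  }
  .writeReport(report, out)
}
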