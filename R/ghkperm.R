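## P_K/P_Na permeability ratios from ion-substitution reversal potentials.

#' Physical constants for the GHK relation
#'
#' @param temperature absolute temperature in kelvin. Default 295.15 K
#'   (22 C, typical room temperature for oocyte recordings); at this
#'   temperature `RT/F` is about 25.43 mV.
#' @param faraday Faraday constant, C/mol.
#' @param gasConstant molar gas constant, J/(mol K).
#' @return Named list of constants.
#' @export
physicalConstants <- function(temperature = 295.15, faraday = 96485,
                              gasConstant = 8.314) {
  .assertScalar(temperature, "temperature", 0, strict_lower = TRUE)
  list(faraday = faraday, gasConstant = gasConstant,
       temperature = temperature)
}

#' Ion condition of the substitution baths
#'
#' The outer concentrations of the single-cation baths. The default 98 mM /
#' 98 mM pair corresponds to equimolar substitution of the sole monovalent
#' cation (98 mM NaCl vs 98 mM KCl).
#'
#' @param naOut,kOut outer \[Na+\] and \[K+\] in mM (> 0).
#' @return Named list with `naOut`, `kOut`.
#' @export
ionCondition <- function(naOut = 98, kOut = 98) {
  .assertScalar(naOut, "naOut", 0, strict_lower = TRUE)
  .assertScalar(kOut, "kOut", 0, strict_lower = TRUE)
  list(naOut = naOut, kOut = kOut)
}

.checkRecords <- function(records) {
  need <- c("erev_na_mV", "erev_k_mV")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records must be a data.frame with columns erev_na_mV, erev_k_mV")
  for (jn in c("junction_na_mV", "junction_k_mV"))
    if (is.null(records[[jn]])) records[[jn]] <- 0
  if (!all(is.finite(records$erev_na_mV)) ||
      !all(is.finite(records$erev_k_mV)))
    stop("reversal potentials must be finite")
  records
}

#' Subtract junction potentials from measured reversal potentials
#'
#' Each measured reversal potential is corrected as measured minus the
#' junction potential of its bath; the junction columns are zeroed in the
#' output so the correction cannot be applied twice.
#'
#' @param records data.frame of reversal-potential records with columns
#'   `erev_na_mV`, `erev_k_mV` and optional `junction_na_mV`,
#'   `junction_k_mV` (default 0).
#' @return The corrected records (same shape, junctions zeroed).
#' @examples
#' correctJunction(data.frame(erev_na_mV = 10, erev_k_mV = 0,
#'                            junction_na_mV = 2, junction_k_mV = 0))
#' @export
correctJunction <- function(records) {
  records <- .checkRecords(records)
  records$erev_na_mV <- records$erev_na_mV - records$junction_na_mV
  records$erev_k_mV <- records$erev_k_mV - records$junction_k_mV
  records$junction_na_mV <- 0
  records$junction_k_mV <- 0
  records
}

#' Permeability ratio P_K/P_Na from a reversal-potential shift
#'
#' Applies the extended Goldman-Hodgkin-Katz flux relation for
#' bi-ionic substitution:
#' \deqn{P_K/P_{Na} = \frac{[Na^+]_o}{[K^+]_o}
#'   \exp\!\left(\frac{\Delta E_{rev} F}{RT}\right), \quad
#'   \Delta E_{rev} = E_{rev}(Na^+) - E_{rev}(K^+).}
#' Records are expected to be junction-corrected ([correctJunction()]); a
#' warning is raised if nonzero junction columns are present.
#'
#' @param records junction-corrected records (see [correctJunction()]).
#' @param cond an [ionCondition()].
#' @param consts a [physicalConstants()].
#' @return data.frame with one row per record: `delta_erev_mV` and `ratio`
#'   (dimensionless P_K/P_Na, always > 0).
#' @examples
#' rec <- data.frame(erev_na_mV = 17.63, erev_k_mV = 0)
#' permeabilityRatio(rec)  # ~2
#' @export
permeabilityRatio <- function(records, cond = ionCondition(),
                              consts = physicalConstants()) {
  records <- .checkRecords(records)
  if (any(records$junction_na_mV != 0) || any(records$junction_k_mV != 0))
    warning("records carry nonzero junction potentials; ",
            "apply correctJunction() first")
  dE <- records$erev_na_mV - records$erev_k_mV
  rtF_mV <- 1000 * consts$gasConstant * consts$temperature / consts$faraday
  data.frame(cell_id = if (is.null(records$cell_id))
               seq_len(nrow(records)) else records$cell_id,
             delta_erev_mV = dE,
             ratio = (cond$naOut / cond$kOut) * exp(dE / rtF_mV))
}

#' Mean, SEM and n of a group of permeability ratios
#'
#' @param x numeric vector (n >= 1).
#' @return list with `mean`, `sem` (sample SD over sqrt(n); `NaN` with
#'   `semDefined = FALSE` for n = 1) and `n`.
#' @examples
#' summarizeGroup(c(1, 2, 3))
#' @export
summarizeGroup <- function(x) {
  if (length(x) < 1L || !is.numeric(x)) stop("need at least one value")
  n <- length(x)
  sem <- if (n >= 2L) sd(x) / sqrt(n) else NaN
  list(mean = mean(x), sem = sem, n = n, semDefined = n >= 2L)
}

#' Wild-type vs mutant comparison with Bonferroni correction
#'
#' Two-sided two-sample Student's t test, equal variances pooled by default
#' (`welch = TRUE` switches to the Welch test). The Bonferroni-corrected
#' p-value is `min(1, pRaw * nComparisons)`, with the number of comparisons
#' per panel supplied by the caller.
#'
#' @param wt,mutant numeric vectors, each of length >= 2.
#' @param nComparisons number of comparisons in the family (>= 1).
#' @param welch logical; use the Welch unequal-variance test instead.
#' @return list with `t`, `df`, `pRaw`, `pBonferroni`.
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6))
#' @export
compareGroups <- function(wt, mutant, nComparisons = 1L, welch = FALSE) {
  if (length(wt) < 2L || length(mutant) < 2L)
    stop("both groups need n >= 2")
  nComparisons <- .assertCount(nComparisons, "nComparisons")
  tt <- t.test(wt, mutant, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       pRaw = tt$p.value,
       pBonferroni = min(1, tt$p.value * nComparisons))
}
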