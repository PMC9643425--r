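# grchannel

Quantitative analyses for insect gustatory receptor (GR) channels — the
class of seven-transmembrane, ligand-gated cation channels exemplified by
the silkworm d-fructose receptor BmGr9. The package implements, as tested
reusable code, the four analyses by which such a receptor is established
to be a homotetrameric, weakly selective, ligand-gated channel with a
defined binding pocket:

* **Stoichiometry from photobleaching.** Single-molecule TIRF spots of a
  GFP-tagged receptor bleach in discrete steps. With each subunit's tag
  fluorescent with probability *P* and dark spots unobservable, the step
  count *k* of a visible n-mer follows the zero-truncated binomial law

  Pr(k | n, P) = C(n, k) P^k (1−P)^(n−k) / (1 − (1−P)^n),  k = 1..n.

  The package detects steps in traces (change-point segmentation plus
  drop quantization), fits *P* by maximum likelihood, and selects among
  candidate subunit numbers (tetramer/pentamer/hexamer by default) with a
  Pearson chi-squared test.

* **Ion selectivity.** From ion-substitution reversal potentials, the
  extended Goldman–Hodgkin–Katz flux relation

  P_K/P_Na = ([Na⁺]ₒ/[K⁺]ₒ) · exp(ΔE_rev · F/RT),  ΔE_rev = E_rev(Na⁺) − E_rev(K⁺)

  with junction-potential correction, per-group mean ± SEM, and
  WT-vs-mutant Student's t statistics with Bonferroni correction.

* **Alignment reliability for homology modelling.** Pairwise alignments
  are scored by the positional consistency of predicted TM segments
  (per-segment Jaccard overlap across alignment columns), and ranked.

* **Binding-site classification.** Docking poses are clustered into
  binding-site types (single linkage on pose centroids), contact residues
  identified by a heavy-atom distance rule, and types ranked by coverage
  of the residues whose mutation abolishes the ligand response.

A synthetic-data module (`simulateStepCounts()`, `simulateBleachTrace()`,
`simulateReversalPairs()`, `generatePoseFixture()`,
`generateAlignmentFixture()`) produces every input with known ground
truth, so the whole pipeline runs and is validated without experimental
raw data. See the methods vignette (`vignettes/methods.Rmd`) for the
models, assumptions, defaults and limitations.

## Worked example

Simulate a single-molecule experiment at the study scale — 569 spots from
a tetramer with per-subunit fluorescence probability 0.776 — then ask
which oligomer model survives:

```r
library(grchannel)

h <- simulateStepCounts(nSpots = 569, nSubunits = 4, pFluor = 0.776, seed = 1)
h
#> StepCountHistogram: 569 spots
#>   1   2   3   4
#>  19  98 244 208

fits <- selectOligomer(h, candidates = c(4, 5, 6), alpha = 0.05)
for (f in fits) show(f)
#> OligomerFit: n = 4, p_hat = 0.7798
#>   chisq = 0.2637, df = 2 (p = 0.8765); df without fitted-p = 3 (p = 0.9667)
#>    retained
#> OligomerFit: n = 5, p_hat = 0.6204
#>   chisq = 90.3, df = 3 (p = 1.893e-19); df without fitted-p = 4 (p = 1.14e-18)
#>    rejected
#> OligomerFit: n = 6, p_hat = 0.5142
#>   chisq = 148.3, df = 4 (p = 4.681e-31); df without fitted-p = 5 (p = 3.053e-30)
#>    rejected
```

Only the tetramer fits the step-count histogram: its fitted fluorescence
probability (0.78) matches the generating value and its chi-squared
p-value is large, while the pentamer and hexamer models predict mass at
step counts that never occur and are rejected outright.

Ion selectivity from fifteen simulated oocytes with 2 mV measurement
noise and a true P_K/P_Na of 2:

```r
rec <- simulateReversalPairs(electroSimConfig(trueRatio = 2, erevNoiseSd = 2,
                                              nCells = 15, seed = 1))
s <- summarizeGroup(permeabilityRatio(correctJunction(rec))$ratio)
sprintf("P_K/P_Na = %.3f +/- %.3f (n = %d)", s$mean, s$sem, s$n)
#> "P_K/P_Na = 2.003 +/- 0.051 (n = 15)"
```

Pose classification on a planted 4/4/2 fixture (the pattern of ten
energy-ranked docking modes falling into three spatial types):

```r
ps <- generatePoseFixture(poseSimConfig(rbind(c(0, 0, 0), c(40, 0, 0),
                                              c(0, 40, 0)), c(4, 4, 2),
                                        seed = 1))
clusterPoses(ps, cutoff = 5)
#> PoseClustering: 3 binding-site types at cutoff 5 A
#>   type 1: poses #1, #2, #3, #4
#>   type 2: poses #5, #6, #7, #8
#>   type 3: poses #9, #10
```

`ligandContacts()` then maps each pose's contact residues against a
receptor PDB, and `rankBindingTypes()` scores each type by the fraction
of response-critical residues (from a mutagenesis table via
`criticalResidues()`) its contacts cover — coverage 1.0 singles out the
true binding site.

A thin command-line front end over the same functions is installed at
`system.file("scripts", "grchannel-cli.R", package = "grchannel")`, with
subcommands `simulate-traces`, `count-steps`, `fit-oligomer`, `ghk`,
`ghk-compare`, `score-alignment`, `cluster-poses`, `contacts`,
`rank-sites`.

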