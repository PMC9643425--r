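---
title: "Models and methods: oligomeric state, selectivity and binding site of a gustatory receptor channel"
author: "grchannel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grchannel)
```

# Scope

Insect gustatory receptors (GRs) such as the silkworm d-fructose receptor
BmGr9 are seven-transmembrane, ligand-gated cation channels. Establishing
that such a receptor works as a homotetramer, which ions it passes, which
template alignment supports a credible homology model, and where its ligand
binds rests on four quantitative analyses, all implemented here:

1. subunit counting from single-molecule photobleaching step histograms
   (conditional binomial model, maximum likelihood, chi-squared model
   selection);
2. permeability ratios from ion-substitution reversal potentials through
   the Goldman-Hodgkin-Katz (GHK) flux relation;
3. positional-consistency scoring of predicted TM segments across pairwise
   alignments;
4. classification of docking poses into binding-site types, and
   concordance ranking against mutagenesis response data.

The package starts from processed observables — per-spot intensity traces,
reversal-potential records, aligned sequences with TM annotations, and
docked poses. Image processing, TM prediction, alignment computation,
homology modelling and docking are upstream tools and out of scope. A
synthetic-data module generates every input with known ground truth, which
is what the test suite and the acceptance script run on.

# Photobleaching stoichiometry

## The conditional binomial model

Each subunit of an n-mer carries one GFP tag that is fluorescent with
probability $P$ (folding/maturation is imperfect). A spot with $k \ge 1$
fluorescent tags bleaches in $k$ discrete steps; a spot with $k = 0$ is
dark and can never be selected for analysis. The observable step count
therefore follows the zero-truncated binomial law

$$\Pr(k \mid n, P) = \frac{\binom{n}{k} P^k (1-P)^{n-k}}{1 - (1-P)^n},
\qquad k = 1, \dots, n.$$

`conditionalBinomialPmf()` evaluates this closed form;
`simulateStepCounts()` samples from it. The conditioning matters: at
$n = 4$, $P = 0.776$ about 0.25% of spots are dark, and ignoring
truncation would bias $\hat P$ downward.

`fitP()` maximizes the multinomial log-likelihood over $P \in (0, 1]$ with
a 1-D golden-section search (`stats::optimize`, tolerance $10^{-9}$),
checking the $P = 1$ boundary explicitly since the optimizer never
evaluates endpoints. Degenerate histograms (all mass at $k = n$, giving
$\hat P = 1$, or all at $k = 1$, driving $\hat P \to 0^+$) are flagged
rather than hidden. A least-squares fit of the proportions is exposed as
`method = "ls"` for comparison; maximum likelihood is the default because
the histogram is a genuine multinomial sample.

## Model selection

`gofTest()` computes the Pearson statistic over bins $1..n$ against
$N \cdot \Pr(k \mid n, \hat P)$. The degrees of freedom are ambiguous when
$P$ is estimated from the same data; we default to
$(\mathrm{bins} - 1) - 1$ and report the unsubtracted convention alongside
(`dfAlt`, `pValueAlt`). Two edge cases are handled explicitly:

* an expected count of zero facing observed mass — including any observed
  step count above $n$, which the candidate model gives probability zero —
  yields an infinite statistic, reported as certain rejection with the
  `emptyExpected` flag;
* a saturated model (2 bins, 1 fitted parameter, df 0) has no usable
  p-value and returns `NA` rather than a fabricated number.

`selectOligomer()` applies fit-then-test to each candidate (default
tetramer, pentamer, hexamer) and retains those with $p \ge \alpha$
(default 0.05). All fits are returned so that ambiguity is visible. At the
study scale — 569 spots, $P = 0.776$ — the tetramer is retained and the
pentamer and hexamer models are rejected in essentially every simulated
replicate; the dominant rejection mode is the pentamer/hexamer's predicted
mass at step counts that are never observed.

## Step detection

The source data for the histogram are per-spot intensity traces. Step
counting in such experiments is traditionally done by visual inspection;
the algorithmic detector here is a package design decision and is
validated exclusively against synthetic ground truth.
`detectSteps()` proceeds in three stages:

1. **Segmentation.** Binary segmentation of the trace under a penalized
   residual-sum-of-squares criterion; the penalty is
   $s \, \hat\sigma^2 \log n$ with $\hat\sigma$ the robust noise estimate
   $\mathrm{MAD}(\Delta x)/\sqrt 2$ and $s$ the `sensitivity` argument
   (default 2). On a noiseless staircase every true step, and nothing
   else, reduces the RSS, so recovery is exact.
2. **Merging.** Adjacent segments whose means differ by less than half
   the median downward drop are re-merged; such sub-half-unit level
   changes are segmentation artifacts, not bleach events.
3. **Quantization.** The remaining drops are modelled as integer
   multiples $m_i u$ of a unit amplitude $u$. The unit is chosen by
   penalized least squares,
   $\min_u \sum_i (d_i - m_i u)^2 + \lambda u^2 \sum_i (m_i - 1)$ with
   $m_i = \max(1, \mathrm{round}(d_i/u))$ and $\lambda = 0.25$, so that a
   double-height drop (two fluorophores bleaching within one frame, which
   happens in a few percent of four-step traces at the default kinetics)
   is counted as two steps, while reading unit drops as doubles requires
   real evidence.

At the generator's default signal-to-noise ratio of 5 (unit steps, noise
SD 0.2) the detector is exact on 95–98% of traces across seeds; residual
failures are bleach events inside the very first frame interval and
coincident double events that leave no usable intermediate level.

## What the generator emulates — and what it does not

`simulateBleachTrace()` draws per-fluorophore bleach times i.i.d.
exponential (standard single-fluorophore photophysics; only the stepwise
structure matters downstream), samples the piecewise-constant level
instantaneously at the frame interval, and adds i.i.d. Gaussian noise.
Defaults are chosen as a realistic single-molecule TIRF scenario: 113
ms/frame acquisition, 8 s mean bleach time, 60 s recording (long enough
that under 0.1% of fluorophores survive the movie), unit step amplitude
and noise SD 0.2. Not modelled: blinking, pre-observation bleaching,
exposure-time integration, camera/PSF effects, or amplitude heterogeneity
between tags. Passing tests therefore certify the inference machinery
under the stated statistical model, not robustness to every optical
artifact of real movies.

# GHK permeability ratios

For bi-ionic substitution between a Na$^+$ bath and a K$^+$ bath (default
98 mM each, the equimolar single-cation pair), the extended GHK flux
relation gives

$$\frac{P_K}{P_{Na}} = \frac{[\mathrm{Na}^+]_o}{[\mathrm{K}^+]_o}
\exp\!\left(\frac{\Delta E_{rev} F}{RT}\right),
\qquad \Delta E_{rev} = E_{rev}(\mathrm{Na}^+) - E_{rev}(\mathrm{K}^+),$$

where the exponent is read as $\Delta E_{rev} \cdot F/(RT)$, the only
dimensionally consistent interpretation. Junction potentials are
subtracted (measured minus junction) by `correctJunction()` before the
ratio is taken; the corrected record zeroes its junction columns so the
correction cannot be applied twice. The recording temperature defaults to
295.15 K (22 °C, typical for oocyte work; $RT/F \approx 25.43$ mV) and is
configurable.

`simulateReversalPairs()` inverts the relation to plant a chosen true
ratio, so generator and estimator are exact inverses at zero noise — the
round-trip is machine-precision for any ratio across two decades. With
measurement noise the per-cell ratio is a convex (exponential) transform
of Gaussian error, so the group-mean estimator carries a small upward
bias, about $+0.6\%$ at 2 mV per-bath noise; the Monte-Carlo tests record
this bias rather than hiding it, and it stays well inside 5% at the study
scale (15 cells).

Group comparison uses the unpaired two-sample Student's t test with
pooled variance (the named test; Welch is available behind `welch =
TRUE`) and Bonferroni correction $\min(1, p \cdot m)$ with the family
size $m$ supplied per panel by the caller.

# TM-segment consistency of alignments

Template alignments for homology modelling of a 7-TM receptor are judged
by whether the predicted TM segments of the two proteins land on one
another across the alignment. No formula for this criterion is standard,
so the package defines one and exposes a variant:

* **Jaccard (default):** for segment pair $i$, the number of alignment
  columns whose residues lie inside segment $i$ on both sequences divided
  by the number of columns where either does. Bounded in $[0,1]$,
  symmetric, and insensitive to segment-length imbalance.
* **Coverage:** the fraction of sequence A's segment-$i$ residues whose
  aligned partner lies inside segment $i$ of B — a directional
  column-count reading of the same idea.

Both are reported per segment and as the mean; segments are paired in
order (S1–S7 for these receptors), with no optimal-matching step.
`rankAlignments()` sorts candidate alignments by overall score with a
deterministic lexicographic tie-break on the source label. On synthetic
fixtures where one annotation is shifted by $d$ residues against a TM of
length $L$, the per-segment score is exactly $(L-d)/(L+d)$ (zero once
$d \ge L$), which makes the monotonicity of the ranking testable by hand.

# Binding-site types and mutagenesis concordance

Docked ligand poses (consumed as multi-model PDB with an affinity
sidecar) are classified by `clusterPoses()`: single-linkage agglomeration
on pose-centroid distances, cut at 5 Å by default. Single linkage is the
defensible reading of classification "by binding position" — poses that
chain together within the cutoff share a site — and its merge structure
is monotone in the cutoff, which the tests exploit. Type ids follow each
cluster's energetically best member, so type 1 always contains pose #1.

Contact residues are defined by a heavy-atom minimum-distance rule
(default 4 Å, boundary inclusive), hydrogens ignored. This is a geometric
approximation standing in for buried-surface-area interface analysis:
computing solvent-accessible-surface bookkeeping is out of scope, and the
4 Å default spans the hydrogen-bond and CH–π range that dominates
protein–carbohydrate recognition. Every report carries this caveat
verbatim in its `contactDefinition` field, and residues are keyed by the
author numbering of the input PDB so that labels like D99 match
mutagenesis tables directly.

`criticalResidues()` thresholds a mutagenesis table at a relative
response of 0.01 (the "response essentially lost" class; 0.5 admits the
partially impaired class as well). `rankBindingTypes()` unions each
type's member contact sets and scores the fraction of critical residues
covered; a coverage of 1.0 reproduces the "every response-critical
residue lies in this site" argument that identifies the true binding
site. Coverage is undefined (an error) for an empty critical set.

# Orchestration and reproducibility

`runStoichiometry()`, `runSelectivity()` and `runPocket()` wrap the three
analyses behind a shared `runConfig()` (CLI > file > defaults precedence,
YAML or JSON) and emit JSON reports embedding the package version, seed
and full configuration; identical inputs produce byte-identical reports.
A thin script (`inst/scripts/grchannel-cli.R`) exposes the simulate /
count / fit / score subcommands for shell use; all logic stays in
exported functions.

Every stochastic routine takes an explicit seed, evaluates under a
temporary RNG state, and restores the caller's stream — there is no
hidden global state, and the same seed always reproduces the same draw.

# Numerical choices and problem sizes

* MLE search interval $[10^{-8}, 1]$ with explicit boundary handling;
  grid-search oracles in the tests pin the optimum to $10^{-4}$.
* Pearson statistics are validated against hand arithmetic to $10^{-10}$.
* The validation suites run at the scales the analyses target: 200
  replicate experiments of 569 spots for estimator bias and model
  selection; 500 traces for detector recovery; 500 simulated experiments
  of 15 cells for the noisy GHK estimator; enumeration oracles up to
  hexamers.

# Known limitations

* The step-count detector is validated against the generator's
  statistical model only; real traces with heavy blinking or drifting
  baselines would need preprocessing upstream.
* The contact rule approximates interface analysis; borderline residues
  near the cutoff can differ from a buried-surface-area definition, which
  is why the flag travels with every report.
* Degrees-of-freedom conventions for the fitted-parameter chi-squared
  test differ across the literature; both are reported, and conclusions
  at the study scale do not depend on the choice.
* The GHK relation used is the bi-ionic reversal-potential form; full
  current–voltage fitting and divalent permeability are out of scope.
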