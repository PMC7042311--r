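---
title: "Inferring per-division mutation and cell survival rates from mutational distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring per-division mutation and cell survival rates from mutational distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutdist)
```

## The problem

A growing tissue — an embryonic cell population, expanding haematopoiesis,
or a tumour — accumulates somatic mutations as cells divide.  Two
quantities drive this process at the single-cell level: the mutation rate
per cell division (`muL` mutations per genome, or `mu` per base pair), and
the per-cell survival rate `beta`, the probability that both daughter
lineages of a division persist, conditioned on the observed lineage not
having gone extinct.  Neither is directly observable from a single bulk
sequencing experiment: the mutational burden of one sample confounds the
two, because many low-mutation divisions and few high-mutation divisions
leave the same total.

Multi-region or single-cell data break the confounding.  Every sample's
clonal mutations are the genotype of the sample's most recent common
ancestor (MRCA) cell, and the intersection of two samples' profiles is
the genotype of a yet earlier ancestral cell.  Because divisions come in
integer numbers, the mutational distances separating these reconstructed
ancestors carry a fingerprint of both rates: `muL` sets the spacing of
the (multi-modal, for large `muL`) distance distribution, and `beta`
sets how much weight drifts to larger distances.

## The probability model

Three ingredients compose the expected distance distribution:

1. **Mutations per division** are Poisson: a lineage gains
   `X ~ Poisson(muL)` novel mutations at each division
   (`probMutationsPerDivision()`).
2. **Non-branching divisions**: a division leaves two surviving lineages
   with probability `beta`, one with probability `1 - beta`.  Alongside
   `r` branching divisions, the number `m` of single-survivor divisions
   is negative-binomial, `choose(r+m-1, r-1) beta^r (1-beta)^m`
   (`probNonBranching()`).
3. **Branching divisions between ancestors**: for a pair of sampled
   lineages in an exponentially growing population, coalescent theory
   for deterministic growth `N(t) = exp(beta t)` gives the interval
   density `f(dt) = exp(-beta dt) exp(-exp(-beta dt)/beta)`
   (`coalescentIntervalDensity()`), which discretised over unit division
   intervals and normalised over positive `r` yields `P(r)`
   (`probBranchingDivisions()`).

Compounding the three gives the distance pmf
(`distanceDistribution()`):

```{r pmf}
p <- modelParams(muL = 1.14, beta = 0.96)
pmf <- distanceDistribution(p)
round(pmf@prob[1:8], 4)
```

All pmfs are evaluated through `dpois()`/`dnbinom()` and assembled in a
collapsed form: the double sum over `(r, i)` reduces to a single sum over
total divisions `i` because the Poisson factor depends only on `i`.  The
likelihood is computed in log space with a log-sum-exp over `i`, so
extreme distances do not underflow.

**Truncation.** The infinite sums are cut at `rMax = iMax = 30` by
default (`truncationLimits()`), a conservative choice for every observed
support in practice; the limits are exposed because the truncated mass
matters below `beta ~ 0.3`.  The pmf support ends at the smallest
distance reaching cumulative mass `1 - 1e-6` (capped at
`10 * iMax * max(1, muL)`).

**Death-rate interpretation.** `beta` relates to a microscopic
per-daughter death probability `alpha` by `beta = (1-alpha)/(1+alpha)`
(`betaFromAlpha()`, `alphaFromBeta()`); `beta = 1/3` (`alpha = 1/2`) is
the homeostatic boundary — smaller `beta` cannot sustain growth.  Values
down to 0.05 are still evaluated (and allowed in the priors) so the
posterior can explore the sub-critical region; the growth threshold is
reported, not enforced.

## From data to a distance histogram

Three input routes produce the same sufficient statistic, a
`DistanceHistogram`:

- **Presence matrices / VCF** (`readProfiles()`): sample profiles are
  sets of mutation identifiers; `buildHistogram()` records both set
  differences `|A \ (A n B)|` and `|B \ (A n B)|` for every unordered
  pair.  Clonality filtering (which variants constitute the sample MRCA)
  is an upstream concern; the simulator's `clonalProfile()` applies a
  cell-fraction threshold of 0.3 by default — the cut-off is exposed
  because published analyses do not state one.
- **Single-cell phylogenies** (`readLineageTree()`,
  `treeDistances()`): branch lengths are integer mutation counts; each
  internal node contributes its two child branch lengths, restricted to
  the earliest `maxBranchings` nodes ranked by mutations from the root
  (a molecular-clock proxy, since calendar times are unavailable).
  Polytomies are resolved as zero-length ladders.
- **Ancestor ages** (`ancestorAgeHistogram()`,
  `ancestralDistanceHistogram()`): the inference-facing construction.
  For each pair of samples the intersection genotype is an ancestral
  cell; its mutational age is counted from the global MRCA of all
  samples, pairs coalescing at the global MRCA are dropped (matching the
  positive-`r` normalisation of the coalescent), and only the 20
  earliest distinct ancestors are kept by default — the same restriction
  used for real developmental phylogenies, which also caps the
  correlated deep tail of the pooled pair distances.

Pooled pair distances are *not* independent: pairs sharing an ancestor
contribute identical ages.  The pair multiplicity is the coalescent
weighting, so it is retained for estimation, but any goodness-of-fit
test must use the number of distinct ancestors as the effective sample
size — `distanceGOF()` takes an `nEff` argument for exactly this
design-effect correction, and the recovery machinery rescales pooled
histograms to `nEff` before computing the composite likelihood, which
keeps credibility intervals meaningful and proposal acceptance rates
healthy.

## Inference

`runMCMC()` is a textbook random-walk Metropolis sampler: flat priors on
`muL` (default `[0.01, 100]`) and `beta` (`[0.05, 1]`), additive uniform
proposals with half-widths 0.15 (`muL`, per-genome scale) and 0.06
(`beta`), out-of-bounds proposals rejected, acceptance by likelihood
ratio, burn-in 200 steps, chain length 4000–5000 by default.  Two
documented choices deserve emphasis:

- **Proposal scale.** The 0.15 half-width pairs naturally with `beta`'s
  0.06 only on the per-genome (`muL`) scale; on a per-base-pair scale it
  would be absurd.  Proposals therefore move `muL`.
- **Initialisation.** The default start is a uniform draw from the
  priors.  The likelihood is multimodal in `muL` — a sub-multiple of the
  true rate aligns every observed peak with a model peak — and a
  +-0.15 random walk cannot cross between modes, so `init = "grid"`
  starts the chain at the best point of a coarse likelihood scan
  (80 log-spaced `muL` values x 15 `beta` values).  All validation
  experiments use the grid start.

`summarizePosterior()` reports post-burn-in medians, central 95%
credibility intervals, and the per-base-pair rate `muL / L` (default
`L = 3e9`).

```{r infer}
set.seed(1)
h <- distanceHistogram(sampleDistances(modelParams(muL = 5, beta = 0.7), 300))
ch <- runMCMC(h, mcmcConfig(nSteps = 2000, seed = 2), init = "grid")
str(summarizePosterior(ch), digits.d = 3)
```

## The simulator

`simulateTissue()` grows a population from one founder cell by a
Gillespie event loop: all eligible cells divide at the same rate, so the
next divider is uniform among them; a division leaves two surviving
daughters with probability `beta` or one with probability `1 - beta`,
and every surviving daughter draws `Poisson(muL)` novel mutations.
Single-survivor divisions replace the cell in place — death never leaves
a lattice vacancy — which realises the effective survival rate
conditioned on non-extinction.  Three modes exist: `well-mixed` (every
cell eligible) and boundary-driven `spatial-2D` / `spatial-3D` lattices
(von Neumann neighbourhoods; only cells with a free neighbour divide).
The full lineage is recorded, so exact sample MRCAs, ancestor ages and
pairwise distances are available (`sampleProfiles()`,
`groundTruthDistances()`, `ancestralCells()`, `sampleGenealogy()`).

Sampling (`takeSamples()`) draws disjoint biopsies: contiguous patches
grown from greedy farthest-point ("maximal-distance") seeds in spatial
mode, uniform cells in well-mixed mode.  Sequencing noise
(`sequencingNoise()`) follows the standard read-count model: depth
`~ Poisson(Z)` (default 100x) and variant reads
`~ Binomial(depth, cell fraction)`, with an optional diploid flag that
halves the fraction — the default leaves fractions unhalved, matching
the haploid bookkeeping of the lineage record.

**What the simulator emulates, and what it does not.** It reproduces
integer-division mutation accrual, effective survival, spatial biopsy
geometry and sequencing noise.  It does not model selection or fitness
changes, punctuated mutational bursts, copy-number change, or
time-varying rates; passing validation therefore certifies the machinery
under the model's own assumptions, not those complications of real data.

## Scale of the validation experiments, and an honest limitation

Validation tissues are 10^4 cells (the motivating analyses used ~10^6),
with 200 single-cell samples per tissue, five replicate tissues per
parameter point, and a 5 x 5 grid over `muL` in `[1, 30]`,
`beta` in `[0.4, 1]`; replication averages over the large
tissue-to-tissue randomness of the earliest clade splits, which
dominates any single genealogy.

At this scale a structural approximation of the model becomes visible.
The coalescent ingredient `P(r)` is derived for *deterministic*
exponential growth; an exact stochastic birth process has a Yule-type
pair coalescent whose branching-depth distribution carries a heavier
(power-law) tail than the exponential tail of the deterministic
approximation.  Empirically (see the simulator test on pair-ancestor
branching depths) the two agree at the bulk level — mode at one
branching division, comparable mass over the first few — but differ by
a total-variation distance of roughly 0.2–0.3.  The consequences,
measured by `recoveryExperiment()` and reported by
`scripts/acceptance.R`, are characteristic: the *ranking* of mutation
rates is essentially perfect (Spearman rho ~ 0.97–0.98) and survival
rates rank well though noisily, but absolute relative errors plateau
around 0.2 for `muL` and 0.25–0.3 for `beta` — the survival rate is
compressed towards the middle of its range.  The model's own derivation
notes that birth–death corrections matter for small populations; those
corrections are out of scope here, so the desk-scale recovery numbers
should be read with this caveat rather than as estimator defects.

On data generated from the model itself (`sampleDistances()`), the
pipeline is well calibrated: 95% credibility intervals cover the truth
at the nominal rate and posterior medians at development-like parameters
(`muL ~ 1.1-1.4`, `beta ~ 0.96-1`) are recovered within a few percent,
as the test suite verifies.

## Signature stratification

For tumour data, per-signature rates come from stratifying distances by
trinucleotide mutational signature.  `fitExposures()` performs the
non-negative least-squares regression of a sample's 96 channel counts on
a signature dictionary (any tab-delimited 96-row matrix;
a synthetic six-signature toy dictionary ships with the package);
signatures with non-zero exposure form the candidate set, and
`assignMutation()` gives a mutation to the candidate whose channel
probability is at least twice every other's, else to `"Other"` — ties
fail the dominance rule by construction.  `stratifiedHistograms()` then
splits every pairwise set difference by stratum; strata partition the
unstratified distances exactly, so per-stratum inference decomposes the
overall rate.  Channel-opportunity (nucleotide-composition) weighting is
intentionally left out: the weights used by published analyses are not
stated, and the unweighted rates are the quantity of interest here.

## Numerical and design notes

- All probability assembly is vectorised over the Poisson index; the
  log-likelihood uses log-sum-exp.  Bit-exact collapse to
  `Poisson(r * muL)` at `beta = 1` is preserved because the degenerate
  negative-binomial weights are exact 0/1.
- `combinationDepth` in `buildHistogram()` defaults to 2 (all sample
  pairs); deeper intersections are available but the iteration scheme
  beyond pairs is deliberately conservative, deduplicating identical
  ancestral genotypes.
- Tumour inputs with copy-number-constant restrictions are handled by a
  single `effectiveL` scaling factor on the genome length rather than a
  segmentation model.
- Every stochastic entry point takes a seed; pipeline outputs embed the
  seed, package version and a configuration hash.
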