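---
title: "Methods: phylogenetically controlled analysis of GC content and oxygen requirement"
author: "oxyGC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetically controlled analysis of GC content and oxygen requirement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyGC)
```

## The scientific problem

Guanine is the base most susceptible to oxidative damage, and replication of
oxidised guanine in DNA causes G:C→T:A transversions, so aerobiosis has long
been expected to *lower* genomic GC content. Non-phylogenetic surveys of
prokaryote genomes repeatedly found the opposite — aerobes with higher GC than
anaerobes. Species, however, are not independent samples: closely related
lineages share both oxygen requirement and GC content by descent, so a
comparison across thousands of genomes can be driven entirely by a handful of
deep clades. oxyGC implements the two standard corrections:

1. **Phylogenetically independent pairwise comparison** — aerobe–anaerobe
   pairs flanking single oxygen-requirement transitions on the tree, compared
   with a two-tailed Wilcoxon signed-rank test; and
2. **Phylogenetic generalized least squares (PGLS)** — regression of
   (log-transformed) GC content on an ordinal oxygen code under a
   Brownian-motion covariance scaled by Pagel's λ.

Both operate on three GC measures per organism: whole-sequence GC, GC at
fourfold degenerate third codon positions (4FDS, the closest thing to a
neutral site class), and GC at zerofold redundant sites (ZRS).

## Site classes

A codon position is *fourfold degenerate* when all four nucleotide
substitutions at that position preserve the encoded amino acid, and
*zerofold* when none does. Classes are computed once per genetic code by
exhaustive substitution (`classifyCodonPosition()`); under the
bacterial/archaeal code (NCBI table 11, the default) exactly 32 codons in 8
families (Leu-CTN, Val, Ser-TCN, Pro, Thr, Ala, Arg-CGN, Gly) have a fourfold
third position.

Two decisions here were genuinely open:

* **ZRS is defined operationally** as the second nucleotide of every non-stop
  codon, not as the degeneracy-computed zerofold set. The two coincide under
  table 11 (every second position of a non-stop codon is zerofold), but they
  need not under other codes, so a strict degeneracy-computed mode
  (`strictZerofold = TRUE`) is provided for sensitivity analysis.
* **Malformed CDSs** (length not a multiple of 3, internal stop codons) are
  skipped, counted and reported rather than repaired: real annotation sets
  contain such records and silently truncating them would bias site counts.
  Codons containing ambiguity symbols contribute no site, and ambiguity
  symbols never enter a GC numerator or denominator.

The orthologue screen (`orthologRatioFilter()`) takes the two
ingroup–outgroup distance ratios of a candidate orthologue pair and keeps the
pair when both are **at or below** the 0.8 threshold. The boundary convention
(≤ keeps) and the ratio definitions are this package's documented
operationalisation; the upstream method describes only the threshold value.

## Distances and trees

`pDistance()` is the proportion of differing sites among compared columns,
with **pairwise deletion**: any column holding a gap or ambiguity symbol in
either sequence is excluded. Percent identity is `100 × (1 − p)`. This is the
mismatch-only identity appropriate for fragmentary 16S sequences, where
alignment gaps usually reflect incomplete assemblies rather than indels;
complete deletion would discard most of the signal in such data.

`njTree()` is standard Saitou–Nei neighbour joining with two conventions made
explicit so results are bit-reproducible:

* ties in the Q criterion join the lexicographically smallest label pair
  (internal nodes are keyed by the smallest tip label in their subtree) —
  deterministic and RNG-free;
* negative branch-length estimates are clamped to zero with the deficit
  transferred to the sister branch, preserving the path length through the
  new node; clamps are reported.

On an additive matrix NJ reproduces the generating tree's distances exactly;
the suite checks this to 10⁻⁹ on random 6–10-tip trees.
`bootstrapSupport()` resamples alignment columns with replacement, rebuilds
the tree per replicate, and reports integer percent support per internal
bipartition of the full-data tree; tips are put in canonical (sorted) order
first so supports are invariant to input permutation.

## Independent pair extraction

The pairing rule is stated by example in the source material, so the package
fixes a normative definition: merge obligate categories into their parent
category (aerobic/anaerobic); collapse every **maximal state-uniform clade**
of the rooted tree into one group; then, processing mixed internal nodes from
the tips toward the root, record one state-change event wherever a node has
unclaimed uniform group children of both states. The event pairs the largest
aerobic group with the largest anaerobic group; at a multifurcation the
remaining opposite-state group children of that node are discarded rather
than paired among themselves, which is conservative but guarantees that no
tip enters two pairs — the property that makes per-pair differences
independent. Adjacency is deliberately *sisters-only*: a group attached one
node higher does not pair across an intervening mixed node. On the package's
worked 13-taxon example this yields exactly three events, including the
within-species strain contrast, and leaves the four "background" anaerobes
unpaired, as intended.

One representative per group is chosen by branch length from the group's
common ancestor: mode `"slow"` takes the shortest path (the slowly evolved
lineage, the primary dataset), `"fast"` the longest (the duplicated
analysis). Ties within 10⁻⁹ fall back to the genome with more annotated
genes, then to the lexicographically smallest label. Slow- and fast-mode pair
sets share event ids by construction, differing only in representatives.

Pairs can be restricted to closely related lineages by a 16S identity
threshold (`filterPairsByIdentity()`, `identityThresholdSweep()`); a pair
lacking an identity is excluded at any positive threshold, with a warning,
and threshold 0 keeps everything.

## PGLS

With tip covariance `C` (root-to-MRCA shared path lengths,
`brownianCovariance()`), Pagel's λ multiplies the off-diagonal entries only
(`lambdaTransform()`): λ = 1 is pure Brownian structure, λ = 0 is
phylogenetic independence. `pglsFit()` computes the GLS estimate
β̂ = (XᵀC(λ)⁻¹X)⁻¹ XᵀC(λ)⁻¹y with X = [1, x], residual variance
σ̂² = RSS_C/(n − 2), and a two-tailed t test on n − 2 degrees of freedom for
the slope. Numerical choices:

* λ is estimated by maximising the full multivariate-normal profile
  log-likelihood over [0, 1] with `optimize()` at tolerance 10⁻⁶; because the
  optimiser never evaluates the exact endpoints, both boundaries are checked
  explicitly so λ̂ can reach 0 or 1 (boundary estimates of 1 are common in
  practice). REML is available (`lambda = "REML"`), and a fixed λ can be
  supplied.
* All solves go through the Cholesky factor of C(λ); a factorisation failure
  is reported with the condition number rather than silently regularised.
* Zero-length terminal branches get a 10⁻⁸ jitter (reported) to keep C(λ)
  positive definite.
* The predictor codes are kept as raw 2/3 ordinals (3 = more
  oxygen-preferring), uncentred, so slopes read as "log-GC change per step in
  oxygen preference". The seven supported contrasts
  (`oxygenContrasts()`) each code one group 3 and one group 2 and drop
  everything else.
* GC is log-transformed on the percent scale with natural base
  (`logTransformGC()`); base and scale are switchable and affect only the
  slope's units, never its sign or p value.
* With λ = 0 the covariance is the diagonal of root-to-tip depths, so PGLS
  coincides with OLS exactly on *ultrametric* trees (all depths equal); on
  non-ultrametric trees λ = 0 is a weighted regression.

An unrooted tree is an explicit error — no silent midpoint rooting — because
`C` is only defined relative to a root.

## Nonparametric tests

`wilcoxonSignedRank()` drops zero differences (the original convention; the
alternative of mid-ranking zeros is not offered because the pipeline's GC
differences are continuous and exact zeros are vanishingly rare), mid-ranks
ties of |d|, and for n ≤ 25 computes the exact two-tailed p as
min(1, 2·min(lower, upper tail)) from the full null distribution of the rank
sum, built by convolution over the tie-adjusted ranks — mathematically the
same as enumerating all 2ⁿ sign assignments, which the test suite does
literally as an independent oracle up to n = 12. Beyond the crossover a
normal approximation with continuity and tie corrections is used; the two
paths agree within 0.01 at the boundary on tie-free data.
`mannWhitneyU()` follows the same pattern with a without-replacement rank-sum
convolution (exact for n₁ + n₂ ≤ 20, oracle = all `choose(N, n1)` labelings).
Crossovers are arguments, not constants.

## What the synthetic data emulate — and what they do not

The generators reproduce the *statistical structure* the analyses assume,
with known ground truth:

* `simulateTree()` — forward Yule process (waiting time Exp(k·b) at k
  lineages, observed one censored waiting period after the last split), so
  the expected stem-inclusive tip age is Σₖ₌₁ⁿ 1/(k·b) exactly; rooted,
  ultrametric, bit-reproducible.
* `simulateOxygenStates()` — exactly `nTransitions` flips on distinct
  uniformly chosen edges, inherited by parity from an anaerobic root. Flips
  are used instead of a continuous-time Markov chain because the analyses
  need a *controlled transition count*, mirroring trees with few
  oxygen-requirement changes; adjacent flips can merge, so recovered events
  ≤ flips.
* `simulateGCTrait()` — y = intercept + slope·x + ε with
  ε ~ MVN(0, σ²·C(λ)): the exact PGLS generative model. Defaults
  (σ² = 1, λ = 1, slope 0) are the null conditions used in the calibration
  experiments.
* `generateCDS()` — codons drawn only from fourfold families, so every third
  position is a 4FDS and every second position a non-stop ZRS; G/C counts at
  both site classes are fixed by rounding, putting realised fractions within
  1/nCodons of target and making the generator's bookkeeping exactly
  re-measurable by `gcAt4FDS()`/`gcAtZRS()`.
* `generate16SPair()` — a pair differing at exactly
  `round((1 − identity/100)·L)` positions, with optional gap columns that
  must not change the mismatch-only identity.

Each generator draws from a named pseudo-random stream derived from the
master seed, so stages can be re-simulated independently.

What passing tests on these data do **not** show: real coding sequences mix
all degeneracy classes and codon-usage bias; real 16S divergence is not
uniform across sites; real oxygen-requirement evolution is not a fixed flip
count; and real GC content is bounded in (0, 1) rather than Gaussian. The
synthetic results validate the *estimators and their calibration*, not any
biological claim about prokaryote genomes. The headline comparative results
from the motivating literature derive from ~2000 curated genomes and are not
recomputed here.

## Problem sizes and runtime choices

The Monte-Carlo experiments are sized so a full run stays comfortable on one
CPU: slope recovery uses 500 replicates of 200-tip Yule trees (true slope 5,
λ = 1, ML estimation; the replicate mean is required to sit within 2
Monte-Carlo standard errors of truth), and type-I calibration uses 1000
replicates of 100-tip trees with λ fixed at the generating value 1, where the
GLS t test is exact and the nominal 5% level must be met while naive OLS on
identical data over-rejects several-fold — the phylogenetic artefact the
package exists to correct. The λ-recovery property (λ̂ ≥ 0.9 when data are
generated at λ = 1, λ̂ ≤ 0.1 at λ = 0, in ≥ 90% of replicates) is exercised
at 150 tips × 60 replicates in the unit suite, a size at which the boundary
behaviour is already unambiguous.

## Known limitations

* The pairing rule resolves multifurcations conservatively (one event per
  mixed node); alternative resolutions could recover more pairs at the cost
  of more intricate independence bookkeeping.
* Events are undirected contrasts; no ancestral-state reconstruction is
  attempted, so multiple transitions along a single branch are invisible.
* PGLS here is bivariate with a single ordinal predictor, as the analysis
  requires; it is not a general phylogenetic regression toolkit (no OU
  processes, no measurement-error models, no phylogenetic logistic
  regression).
* Orthologue *detection* is out of scope: the ratio filter assumes distances
  for candidate pairs are supplied.
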