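---
title: "Split-based congruence, saturation and rogue diagnostics for multigene phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-based congruence, saturation and rogue diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhyloCongruence)
library(ape)
```

# Motivation

Multigene phylogenetic studies routinely have to answer a set of questions
that sit *around* the tree inference itself: how much usable signal does each
gene or codon-position partition carry, is any partition saturated or
compositionally biased, how concordant are the tree samples recovered from
different partitions, and are there rogue taxa whose unstable placement
erodes consensus support?  PhyloCongruence implements this assessment layer
as reusable, tested functions, together with a simulator so that every stage
can be exercised on data with known structure.

The taxon-by-gene accession matrix of a seven-gene, 137-taxon Hymenoptera
supermatrix (110 ingroup species in 66 families and 22 superfamilies, plus
27 outgroups) ships as a plain-text fixture and drives the coverage-census
examples.

# Statistics implemented

## Alignment-level signal

For an alignment partition the package reports the number of sites, the
variable sites (at least two distinct unambiguous bases), the
parsimony-informative sites (at least two bases each in at least two taxa),
per-taxon and pooled GC content, and a chi-square test of base-compositional
stationarity across taxa.  The stationarity statistic is the standard
homogeneity chi-square on the taxon-by-base count table: expected counts are
the pooled base frequencies scaled to each taxon's total, with
$(T-1)(B-1)$ degrees of freedom, no continuity correction, and raw
per-partition p-values (no multiplicity adjustment — partitions are reported
side by side, as in the data-property tables such analyses print).

**Gap and ambiguity policy.** Throughout the alignment statistics the only
character states are `A`, `C`, `G`, `T`; gaps (`-`), missing data (`?`) and
IUPAC ambiguity codes are non-states.  This matches the common PAUP*/MEGA
default, but the tools those tables originally came from do not document
their exact treatment of gapped columns, so this is an assumption of the
package, implemented as a single consistent rule: non-states never
contribute to site classes, composition, the stationarity table, or
p-distances (which use pairwise deletion and report the per-pair count of
comparable sites).

## Saturation

Substitution saturation shows as uncorrected p-distances plateauing while
tree (patristic) distances keep growing.  The pipeline pairs each
partition's p-distances with the patristic distances on that partition's own
best tree and reports the pairs plus a single scalar: the least-squares
slope through the origin.  The scalar is a convention of this package (the
original practice is to inspect the plot); an unsaturated partition at small
distances has slope near 1, a saturated one much less.  The partition's tree
must carry branch lengths on that partition's own scale — a tree estimated
from a different, slower partition would move apparent saturation into the
slope.

## Congruence between tree samples: ASDSF

The topological distance between two or more tree samples is the average
standard deviation of split frequencies: for every non-trivial bipartition
whose frequency reaches `minFreq` (default 0.10, mirroring the MrBayes
`minpartfreq` convention) in at least one sample, take the standard
deviation of its per-sample frequencies — with the $n-1$ denominator, the
convention used by the MrBayes `sumt` machinery these values are usually
read from — and average.  A split absent from a sample counts as frequency
0 there.  Identical samples give exactly 0, and for two samples the value is
bounded above by $\sqrt{2}/2 \approx 0.7071$.  The case of no split passing
`minFreq` is an error, deliberately distinct from an ASDSF of 0.

Samples over different taxon sets must first be restricted to shared taxa
(`restrictSample()`), which prunes each tree, suppresses degree-2 nodes and
sums the incident branch lengths, so that pruned split sets equal restricted
split sets.

Splits whose between-run standard deviation exceeds 0.1
(`flagUnstableSplits()`) deserve a question mark in any figure: their
support may not be estimated accurately even when the overall ASDSF looks
converged.

## Consensus and resolution

`majorityConsensus()` keeps exactly the splits with frequency *strictly*
greater than the threshold (default 0.5).  Thresholds at or above 0.5
guarantee pairwise compatibility, which is why thresholds below 0.5 are
refused rather than silently greedily extended; the strict inequality makes
a 50/50 split drop out deterministically.  Support values on the consensus
equal the split frequencies exactly — they are the same numbers, not a
recomputation.  Resolution is $100\,k/(n-3)$ for $k$ retained splits on $n$
leaves: the percentage of internal edges of a fully resolved unrooted
binary tree that the consensus realises.

## Burn-in and subsampling

`subsampleTrees()` discards the first $\lfloor bN \rfloor$ trees (default
$b = 0.25$) and then takes `nOut` evenly spaced trees, always including the
first and last post-burn-in tree when `nOut >= 2`; fractional spacing ties
resolve toward earlier indices.  With 4000 trees, 25% burn-in and 1000 kept
this reproduces the "1,000 evenly spaced post-burn-in trees" input
convention of rogue-taxon analyses.

## Rogue taxa

A rogue is a taxon whose placement varies so much across a tree sample that
removing it *raises* the summed majority-rule support of the consensus.
`supportGain()` scores a dropset as the sum of consensus split supports
after restriction minus the sum before (support units; frequencies in
$[0,1]$).  `findRogues()` runs a greedy outer loop: score all singletons
exhaustively, grow larger dropsets (up to `maxDropsetSize`) by best-first
extension of the top `beamWidth` singletons, accept the best candidate if
its raw improvement reaches `minRawImprovement` (default 0.5 support units),
remove those taxa and repeat.  Ties break toward smaller dropsets, then
lexicographically smaller label tuples, so reports are deterministic.

Design notes:

* Greedy-with-beam rather than exhaustive search: published experience with
  dropset optimisation is that maximum dropset sizes of 2, 3 and 10 identify
  the same rogues, so the extra work of exact search buys little; the test
  suite verifies exact agreement with exhaustive search on samples of up to
  8 taxa and dropsets up to size 2, which is where exactness is checkable.
* "Relative improvement" is not defined by the sources that print it; this
  package reports raw improvement divided by the pre-drop total support and
  labels that a package convention.
* Restriction of a sample for scoring is done on the split sets directly
  (remove dropped taxa from each side, re-canonicalise, de-duplicate within
  each tree), which is equivalent to pruning every tree and recounting but
  considerably faster; the equivalence is property-tested.

# The synthetic-data generator

`simTree()` draws a Yule topology and overwrites branch lengths with
exponential draws (default mean 0.1 substitutions/site — a mid-range
branch length for multigene data at family/superfamily depth).
`simAlignment()` simulates site-wise evolution under GTR+Γ+I: four
equal-probability discrete-gamma rate categories, invariant sites with
probability `pInv`, transition probabilities from the eigendecomposition of
the scaled GTR generator.  Two deliberate extensions support the test
suites:

* a `rateMultiplier` to produce saturated partitions (and, at 0, the
  degenerate all-identical alignment), and
* `gcDrift`, which moves the stationary GC share on the logit scale by
  `drift × branch length` in an independently random direction per edge,
  producing the lineage-specific compositional non-stationarity the
  chi-square test is meant to catch.

`simTreeSample()` emulates a posterior tree sample by applying a fixed
number of random NNI moves per draw, then pruning each listed rogue leaf
and reattaching it at the midpoint of a uniformly chosen edge (pendant
length = the median pendant length, a neutral choice).  NNI perturbation is
a stand-in for MCMC: it reproduces the *inputs* the congruence and rogue
statistics consume — samples with controllable topological spread — not the
correlation structure of a real chain.  Consequences verified as trends in
the tests: expected ASDSF increases, and expected consensus resolution
decreases, with the number of NNI moves.

`simPresenceMatrix()` fills a taxon-by-gene matrix with independent
Bernoulli presences at a target coverage (the shipped study matrix has 84%).

What the generator does *not* emulate: indels (constraint-extraction tests
build gapped alignments directly), codon structure, among-partition linkage,
and MCMC autocorrelation.  Tests passing on these synthetics therefore
demonstrate the correctness of the statistics, not the behaviour of real
posterior samples.

# Stationarity-test calibration

The chi-square homogeneity test ignores phylogenetic correlation: at shallow
divergence all taxa inherit most sites unchanged from the root, compositions
are far more similar than independent multinomial sampling predicts, and the
test is conservative.  The package's calibration test therefore uses the
regime where the test's own asymptotics apply — a star tree with deep
branches (length 10 at rate 1), under which each taxon's composition is an
essentially independent draw from the stationary distribution.  There the
empirical rejection rate at α = 0.05 sits within binomial noise of 0.05
over 1000 replicates, and power against strong GC drift (`gcDrift = 0.5` on
the same tree) exceeds 0.9.  On shallow trees users should expect the test
to under-reject; this is a property of the statistic, not of the
implementation.

# Constraint extraction and coverage census

`extractConstraints()` reproduces the bespoke step of a semi-objective
ribosomal alignment protocol: finding length-constant stem regions of at
least 10 bp in a secondary-structure reference alignment and fixing one
conserved anchor base in the middle of each.  "Length-constant" is not
formally defined by the protocol's description; this package interprets it
as *gap-free in every taxon across the run* (no indels anywhere), with gaps
breaking a stem run into sub-runs that must individually reach `minLen`.
The anchor is the most conserved column (highest modal-base fraction), ties
broken by proximity to the run midpoint (even-length runs resolve to the
lower-middle column), then by lower index — a deterministic reading of
"a conserved base in the middle".  The published counts of 48 (18S) and 85
(28S) constraints cannot be checked without the unpublished reference
alignment, and are not asserted anywhere.

`coverageStats()`/`taxonCensus()` implement the sampling census.  On the
shipped fixture they reproduce the published numbers: 84% overall coverage,
100/100/92/85/61/76% for 18S/28S/CO1/EF1α-F2/EF1α-F1/POL, 75% EF1α-F1
within the ingroup, about six genes per taxon, and 110/27/66/22
species/outgroups/families/superfamilies.  One printed figure is internally
inconsistent with its own table: the prose says 80% for CAD, but the table
carries 31 missing CAD cells, i.e. 106/137 = 77%; the package reports what
the table yields.  (The 66-family count requires tagging *Cales* — printed
under its subfamily name Calesinae — with its family Aphelinidae.)

# Numerical and interface choices

* Column coordinates are 1-based closed intervals everywhere user-facing.
* `U` normalises to `T` on input; `.` is read as a gap; case is folded.
* Bipartitions are canonicalised as the side not containing the
  lexicographically smallest taxon, so split identity is stable across
  rootings and tree orderings; all split computations unroot first.
* Across-sample SDs use the sample ($n-1$) denominator.
* NEXUS support covers DATA/CHARACTERS and TREES blocks (with translate
  tables resolved); other blocks are ignored with a warning.  Tree-sample
  files are accepted both as plain Newick lists and as NEXUS TREES blocks,
  since comparison scripts in this literature have consumed both; parsing is
  dialect-strict, never silently re-interpreted.
* All generators take explicit integer seeds and are bit-reproducible;
  `runFull()` writes a manifest of settings and output checksums, and
  reruns with the same configuration are byte-identical.

## Problem sizes used in the tests

The suites run on deliberately small instances chosen to keep the whole
test run around a minute while leaving the statistics in their asymptotic
regimes: 4–43-taxon trees, samples of 10–500 trees, alignments of 120–2000
sites, 1000 replicates for the calibration study, 30 replicates × 2000
sites per depth for the Jukes–Cantor check.  These sizes are statements
about where the oracles are sharp, not limits of the implementation; the
split machinery is routinely exercisable on hundreds of taxa and thousands
of trees.

# A worked example

```{r example}
tree <- simTree(12, seed = 1)
run1 <- simTreeSample(tree, 80, nniMoves = 1, seed = 2)
run2 <- simTreeSample(tree, 80, nniMoves = 1, rogues = "t3", seed = 3)

asdsf(list(run1, run2))

cons <- majorityConsensus(run2)
resolutionPercent(cons)

rogueTable(findRogues(run2, maxDropsetSize = 2))
```

# Known limitations

* The rogue search is exact only at oracle-tested scale; for larger dropsets
  it inherits the usual greedy caveats (a synergistic dropset none of whose
  subsets helps can be missed).
* The stationarity test's nominal level is only reached when taxa are
  effectively independent (see above).
* No indel simulation; no amino-acid or codon models; NNI pseudo-posteriors
  do not model chain autocorrelation.
* The saturation slope summarises a plot; inspect the pairs for non-linear
  structure before quoting the scalar.
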