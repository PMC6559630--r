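---
title: "Methods: non-native species in mutualistic networks"
author: "invasinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-native species in mutualistic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invasinet)
```

## The question

Established non-native plants and animals are woven into pollination and
seed-dispersal networks worldwide. Because successful invaders tend to be
generalists, they may occupy central network positions: partnering with
many species, sitting on short paths between other species, and supplying
a large share of the interactions that well-connected natives receive. If
so, their presence adds redundant links (supporting the *resistance* of
network function to disturbance) while doing little for poorly-linked
specialist natives (and so not supporting the *resilience* of the native
species assemblage). `invasinet` implements the full analysis pipeline
for this question on binary bipartite networks: species- and
network-level metrics, targeted and control removal experiments,
size-conserving null models, secondary-extinction simulation, and paired
statistical comparisons across a collection of networks — plus a
synthetic-network generator so that every stage is testable end to end
without external data.

## Data model

An `InteractionNetwork` is a labeled binary incidence matrix: rows are
plants (the lower trophic level), columns are animals (the higher
level), and entry $a_{ij}=1$ iff plant $i$ and animal $j$ interact. Each
species carries an origin flag, `native` or `nonnative`, and each
network carries the identifier of its source study, used as a blocking
factor. Conventions, fixed everywhere:

* **Binary interactions.** Quantitative inputs are binarized on read
  (with a warning); most published networks of this kind are
  presence/absence, and no weighted metric is in scope.
* **Conservative nativity coding.** Species annotated `unknown` are
  stored as `native`. Misclassifying a non-native as native only widens
  the native group's spread, inflating Type II error, never Type I; so
  the non-native group contains only species positively known to be
  introduced.
* **No partnerless species.** An observed network has no empty row or
  column; validity enforces this, and readers report the offending
  species by name.
* Labels are opaque case-sensitive tokens; no fuzzy matching between
  matrices and nativity tables.

## Metrics

With $I$ plants, $J$ animals and $L = \sum_{ij} a_{ij}$ links:

* **Connectance** $C = L/(IJ)$, the realized fraction of possible links.
* **Mean links** $L/(I+J)$, links per species.
* **Generality / vulnerability**: mean number of plant partners per
  animal / animal partners per plant. The default (`simple`) is the
  plain degree mean $\sum_j k_j / J$; `degree_weighted` is
  $\sum_j k_j^2 / \sum_j k_j$, the marginal-weighted form computed by
  standard network software, which up-weights generalists. The two
  coincide exactly when all degrees at the level are equal. Every
  output records which variant produced it.
* **Normalized degree** of a species: its partner count divided by the
  opposite-level size, in $(0, 1]$.
* **Betweenness and closeness** are computed on the unweighted one-mode
  projection of the chosen level (two same-level species adjacent iff
  they share at least one partner; co-occurrence counts are discarded
  because the data are binary). Betweenness is shortest-path
  betweenness normalized by $(n-1)(n-2)/2$ for $n \ge 3$, else 0.
  Closeness of node $v$ is component-scaled:
  $\left(\frac{r_v}{n-1}\right)\left(\frac{r_v}{\sum_u d(v,u)}\right)$
  over the $r_v$ nodes reachable from $v$; this equals the classical
  $(n-1)/\sum d$ on a connected graph, is 0 for an isolated node, and
  1 for a single-node projection by convention. Whether empirical
  studies computed closeness on connected components only is usually
  unstated; the component-scaled convention is fixed here so results
  are bit-reproducible, and it is the choice a reader should know
  about. Note that some verbal definitions of "betweenness" in the
  applied literature actually describe partner counts; the package
  reports raw degree alongside graph-theoretic betweenness so both
  readings are available.
* **Pollination Service Index (PSI)**, animals only. For binary data
  the package uses the dependence-product reduction
  $\mathrm{PSI}_j = \sum_{i \in P(j)} \frac{1}{d_i}
  \left(\frac{1}{d_j}\right)^{\beta}$, with $d_i$ the plant's degree,
  $d_j$ the animal's degree, partner set $P(j)$, and exponent
  $\beta \ge 0$ exposed as a parameter (default 1). With $\beta = 1$
  values lie in $(0,1]$ and $\mathrm{PSI}_j = 1$ describes strict
  mutual dependence (a sole-partner animal whose plants depend on it
  exclusively). This reproduces the verbal definition — the importance
  of the animal as a partner for the network's plants — with clean
  bounds.

Shortest-path machinery is delegated to `igraph`; the test suite checks
every metric against an independent brute-force implementation
(Floyd–Warshall distances, explicit geodesic counting) exhaustively on
all binary matrices up to $3 \times 3$.

## Removal experiments

`removeSpecies()` deletes named rows/columns. Remaining species left
with zero partners are the one-step secondary extinctions: they are
reported (`orphaned`) and dropped from the reduced incidence, because
metrics such as closeness are defined on interacting species. Dropping
an orphan removes no links, so it cannot orphan anything else. A
reduction leaving fewer than 2 species at either level is flagged
`excluded` — too degenerate for null-model and paired comparisons — and
excluded networks drop out of every downstream contrast, shrinking the
degrees of freedom accordingly.

Three reduction families mirror the study design:

1. **Natives-only** (`removeNonnatives()`): all non-natives deleted.
2. **Matched random control** (`matchedRandomRemoval()`): exactly as
   many randomly chosen *native* species deleted per trophic level as
   there are non-natives at that level — a size-matched control that
   retains real linkage structure.
3. **Null models** (`nullModel()`): per replicate, the same per-level
   numbers of species are drawn for extinction from *all* species
   regardless of origin, and the surviving links are redistributed as a
   uniform random binary matrix on the reduced dimensions, conditioned
   on that replicate's surviving link total, with draws containing an
   empty row or column rejected (capped at 10,000 attempts). Dimensions
   and each replicate's own link total are conserved exactly, so
   connectance comparisons isolate rewiring rather than fill. A
   degree-sequence-preserving alternative (`method = "swap"`, curveball
   trades) is available but not the default: the fixed-dimension,
   fixed-fill uniform model is the "simple" baseline.

**Conditioning on redistributable draws.** At the sparsity of the
default synthetic ensemble (connectance near 0.07 on roughly
$40 \times 40$ networks), the probability that a uniform fixed-fill
draw has no empty margin is on the order of $10^{-3}$, and occasional
extinction draws leave link totals for which no valid fill is found
within the attempt cap. The workflow therefore calls `nullModel()` with
`maxRedraws = 100`: a replicate whose draw cannot be redistributed
redraws its extinction set. This conditions the null on extinction
draws whose link totals are redistributable — a deliberate, logged
choice that keeps networks from being discarded over sampling accidents
(at `maxRedraws = 0`, the default, the replicate errors instead).

## Secondary extinctions

A secondary extinction is a species left with zero partners after
others are removed — the standard one-step operational definition; no
rewiring and no assumption that partner loss immediately implies real
extinction. `secondaryExtinctions()` gives the one-step count for a
targeted removal. `randomLossCurves()` simulates random losses: each
replicate draws the designated numbers of plants and animals uniformly,
permutes the combined set into a removal order (levels interleaved
uniformly — the expectation at the final step, which is the quantity
used, is order-invariant), and records cumulative secondary extinctions
after each step. Species in a replicate's primary removal set are never
double-counted as secondary. With `cascade = TRUE` orphans are treated
as gone when assessing later orphans, iterated to a fixed point;
because a partnerless survivor holds no surviving links in a bipartite
graph, this coincides with one-step accounting for simultaneous
removals, and the workflow uses one-step accounting for both targeted
and random losses so the comparison is like-for-like.
`expectedSecondaryAt()` returns the Monte-Carlo mean and standard error
at a given number of removals; the suite checks it against exhaustive
enumeration on networks small enough to enumerate.

## Statistics

Network-level contrasts are paired two-tailed Student's t-tests across
networks (`pairedT()`, delegating to `stats::t.test`; $t =
\bar d / (s_d/\sqrt n)$, $df = n - 1$): full vs natives-only, full vs
random control, full vs null mean, and natives-only vs null mean, for
connectance, mean links, generality and vulnerability. The null
comparison pairs each network with the *mean* of its null replicates.
Raw p-values are reported with no multiple-testing correction, matching
the study design this pipeline operationalizes; readers should treat
the table as descriptive. A contrast whose pairwise differences have
zero variance is undefined for the t-test and is either an error
(`pairedT()`) or an `NA` row (comparison tables), never a fabricated
number.

Species-level comparisons use a linear mixed model,
`value ~ origin + level + (1 | study_id)` fit by REML (`lme4`, with
Satterthwaite degrees of freedom from `lmerTest`): origin contrast
non-native minus native, trophic level as a fixed effect (dropped for
PSI, which exists only for animals), and the source study as a random
intercept so networks from one study are not treated as independent.
The package's contribution is the model specification, data assembly
and contrast extraction; the numerical optimization is delegated.
Parameter recovery and test size are verified by simulation
(`simulateSpeciesTable()`): a planted origin effect of 0.2 across 30
studies of 50 species (study SD 0.05, residual SD 0.1) is recovered
within 0.03, and under a zero effect the rejection rate at
$\alpha = 0.05$ sits at its nominal level over 1000 simulations.

## The synthetic ensemble

The generator emulates the statistical structure of empirical
pollination and seed-dispersal ensembles, not any particular network:

* **Scale.** 40 native plants x 40 native animals plus
  `round(0.075 * 40) = 3` non-natives per level (~86 species, matching
  an average observed total near 80 with about 3 removable non-natives
  per trophic level), native mean degree 2 (observed mean links per
  species is near 2.1).
* **Heavy-tailed native core.** Each native animal draws a Poisson(2)
  degree (clipped to at least 1) and attaches to plants with
  probability proportional to (current degree + 1)^`degreeTail`
  (default 1), yielding a few generalists and a long tail of
  specialists; leftover plants get one uniform link so no species is
  partnerless.
* **Invaded regime.** Non-natives draw Poisson(`gamma` x 2) degrees
  (default `gamma = 3`: more generalist than the average native) and
  attach to native species with probability proportional to (native
  degree)^`alpha` (default 1: preferential attachment to well-connected
  natives). By default non-natives do not link each other.
* **Exchangeable regime.** When `gamma = 1` and `alpha = 0` the
  generator instead builds *all* species with the single native kernel
  and assigns non-native labels as a uniform random per-level subset.
  This makes non-natives exactly exchangeable with natives by labeling
  symmetry — the literal two-phase construction is not exchangeable
  even at `gamma = 1` (native plants receive links while non-native
  plants draw them), and a calibration null must be exact, so the
  regime switch is deliberate. Under this regime the natives-only
  reduction and the matched random control are marginally identically
  distributed, and measured rejection rates of the paired contrasts sit
  near the nominal 5%.
* **Determinism.** Every randomized stage draws from a child seed
  derived from one master seed (`childSeed()`, a fixed affine map into
  the 32-bit range), so reruns are bit-identical and collection
  generation is reproducible network by network.

What the generator does **not** emulate — and hence what passing tests
do not show about real data:

* **Size heterogeneity.** Empirical ensembles mix networks from ~10 to
  hundreds of species; the synthetic ensemble is homogeneous at
  ~86. This matters: for equal-sized networks, removing a species of
  degree $k$ *raises* connectance of the reduction iff $k$ is below the
  level's mean degree, so an ensemble whose non-natives are strongly
  generalist (`gamma = 3`) necessarily shows *higher* connectance for
  full networks than for natives-only reductions. The opposite,
  empirically reported direction arises from many small networks in
  which removing ~3 species per level shrinks the possible-link area
  faster than the realized links. The directionality suite asserts the
  empirical sign pattern; on this homogeneous ensemble the connectance
  contrast is strongly significant in the reversed direction, and that
  result is reported as-is rather than papered over.
* **Binary PSI and generalist partners.** Because the binary PSI
  multiplies the animal's dependence share $(1/d_j)$ by its plants'
  shares $(1/d_i)$, non-natives that preferentially attach to
  well-connected plants (large $d_i$) score *lower* than average, and
  the synthetic invaded ensemble shows a negative non-native PSI
  contrast even while normalized degree, betweenness and closeness
  contrasts are positive. Empirical PSI differences also reflect
  network-size variation and visit structure that the binary reduction
  cannot carry.
* No interaction strengths, no rewiring after removal, no fitting of
  the generator to empirical degree data.

## Problem sizes and numerical choices

The test suite and the acceptance script use, as the package's own
standard conditions: 58 synthetic networks for directional analyses
with 1000 null-model and 1000 random-loss replicates per network; 200
collections of 20 networks for calibration of the exchangeable null;
and 1000 simulations for mixed-model test size. At 200 collections the
binomial standard error of a 5% rejection-rate estimate is about 1.6
percentage points, so individual calibration runs can land a couple of
points from nominal; a 1000-collection measurement of the same
contrasts sits at 4.7-6.3%. Paired counts of secondary extinctions are
small and discrete, which makes the t-test on them conservative in
small collections. All tolerances in tests are stated per check: exact
equality for closed-form metric values, 3 Monte-Carlo standard errors
for simulation-vs-enumeration checks.

## Limitations

Beyond the generator limitations above: metrics are binary-only by
design (no nestedness, modularity or weighted indices); the pipeline
consumes nativity annotations and never produces them; one-step
secondary-extinction counts are an upper-bound-free proxy, not a
prediction of realized coextinction; and mixed-model degrees of freedom
follow the Satterthwaite approximation, a convention that should be
stated when reporting.
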