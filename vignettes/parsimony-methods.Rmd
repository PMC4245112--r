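---
title: "Methods: equally-weighted parsimony, search, and clade support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equally-weighted parsimony, search, and clade support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladesearch)
```

This vignette is the package's own account of what it computes and why the
pieces are built the way they are. It is written for a systematist who
wants to know exactly what happens between "here is my matrix" and "here is
the support-annotated consensus".

## The optimality criterion

A character matrix assigns each taxon, for each character, a set of allowed
states: a singleton for an ordinary observation, a larger set for a
polymorphic cell, and — after normalization — the full set of states
observed in that character for missing (`?`) and inapplicable (`-`)
entries. Treating `?` and `-` identically is the standard equally-weighted
convention: under best-case resolution such cells can never contribute
steps, and nothing in an unweighted Fitch/additive framework distinguishes
"not preserved" from "not applicable". Every routine in the package
(lengths, minima, star maxima, simulation masks) uses this single
normalization, so the invariants m&#7522; &le; s&#7522; &le; g&#7522; hold by
construction.

The length of a tree is L = &Sigma; w&#7522;s&#7522;. For unordered
characters s&#7522; is the Fitch minimum (any change costs one step); for
ordered (additive) characters the cost of changing from a to b is |a-b|.
Both are computed exactly by dynamic programming over the &le; 10 states;
the DP formulation also scores polytomous trees directly, which the
rule-1 collapse and consensus diagnostics need. Parsimony length is
invariant to rooting, so all trees are handled unrooted; display rooting is
cosmetic. Binary trees in the hot paths use bitmask Fitch sets instead of
the DP, which is exact there.

Per-character bounds used by the fit indices:

* m&#7522;, the minimum conceivable steps on *any* tree: for unordered
  characters the minimum number of states that intersects every cell
  (a minimum hitting set, found exactly by brute force over the &le;
  2&sup1;&#8304; state subsets) minus one; for ordered characters the
  smallest achievable state range.
* g&#7522;, the length on the completely unresolved star tree: for
  unordered characters n minus the best single-state cover; for ordered
  characters min&#8324; &Sigma;&#7522; min&#8339;&#8712;cell |x-y| over the
  candidate median states y.

The ensemble consistency index CI = &Sigma;m/&Sigma;s and retention index
RI = (&Sigma;g-&Sigma;s)/(&Sigma;g-&Sigma;m) are reported over **all**
characters as the primary statistic — the convention of the standard TNT
statistics scripts, whose output published studies typically quote — and
over parsimony-informative characters only (g&#7522; &gt; m&#7522;) as a
secondary variant, since sources rarely say which convention they used.
Both are always computed; a study report records both.

## Exact search

`exact_search()` is a branch and bound over leaf-addition sequences: a
three-taxon core grows one taxon at a time, each insertion on every branch,
and a partial tree is abandoned when a lower bound on any completion
exceeds the best length seen (plus the user's slack). Because the pruning
test is strict, every optimal (and within-slack) binary tree is returned —
the result is independent of the addition order, only the runtime is not.

Three implementation choices matter for speed and are worth documenting:

* **Addition order.** Taxa are added in a deterministic farthest-first
  order (most-conflicting rows first), which makes partial lengths grow
  early and prunes harder than matrix row order; members of any
  require-monophyly constraint go first, so the partial monophyly check
  binds from the top of the search tree. Row order was measured minutes
  slower at the 16 &times; 110 scale this package targets.
* **Incremental scoring.** One pass over the current partial tree computes
  directional state sets (cost vectors for ordered characters) for both
  sides of every branch; the length of each candidate insertion then
  follows in O(1) per character from the Fitch edge-set rule, rather than a
  full rescore per candidate. The rule is verified against full rescoring
  in the test suite.
* **The lower bound.** Per character, a completion can never need fewer
  than max(s&#7522;(partial), m&#7522;) steps, because per-character length
  is monotone under leaf addition and never below the over-all-trees
  minimum. On top of that, provably incompatible binary character pairs
  (all four state combinations present among cells determinate in both)
  jointly need at least m&#7522;+m&#11388;+1 steps on any tree; a greedy
  disjoint matching of such pairs is added to the bound. A classic
  alternative — counting states the unplaced taxa must introduce beyond the
  placed rows' minimum cover — is **not** admissible once `?` cells
  normalize to observed-state sets (a full-tree optimum may use more states
  on the placed rows than their own minimum cover), and is not used; the
  property suite that compares the search against exhaustive enumeration
  is what caught this.

The incumbent is seeded from a short heuristic pass under a fixed internal
RNG state (the caller's RNG is saved and restored), which only tightens
pruning and cannot exclude optima. Constraints are enforced during growth
for require-monophyly (a partial tree whose placed members cannot form a
clade is cut immediately) and at completion for forbid-monophyly. The
practical guard is 20 taxa; beyond that `heuristic_search()` is the tool.

## Heuristic search

`heuristic_search()` builds stepwise-addition trees under random taxon
orders, refines each by first-improvement TBR branch swapping (the TBR
neighborhood contains all SPR moves), and then closes the retained set
under TBR moves that stay within the slack of the best length — this
plateau sweep is what finds co-optimal trees, which the bootstrap's
per-replicate strict consensus needs. All randomness comes from R's RNG,
so a seed makes the whole search reproducible; there is no global-state
mode, the seed argument is mandatory. Constraints enter as large additive
penalties during construction and swapping, and infeasible trees are
discarded at the end.

## Collapse, consensus, support

**Rule-1 collapse.** A branch is collapsed when its minimum length over all
most-parsimonious reconstructions is zero, which is equivalent to: the tree
length is unchanged when the branch is contracted. Individually ambiguous
branches can be mutually exclusive (each has a zero-length reconstruction
but no reconstruction zeroes both), and contracting all of them at once can
lengthen the tree; the implementation therefore iterates — contract,
rescore, re-test — to a fixpoint, which preserves length by construction
and leaves no zero-minimum branch. Searches collapse their trees first and
deduplicate by bipartition-set equality second, so two optima that collapse
to the same polytomous tree count once.

**Strict consensus** is the tree whose splits are exactly the intersection
of the input trees' split sets, built from the package's canonical
bipartition representation (the side not containing the reference taxon,
as a bitmask); it is cross-checked against an independent implementation in
the tests.

**Bremer decay.** d(clade) = (best length among trees in which the clade is
not monophyletic) minus the optimum, computed by an exact search under the
converse constraint. The equivalent route — raising the slack until a
retained tree lacks the clade — is implemented too, and the two are
asserted equal on randomized matrices. For a group absent from the strict
consensus the index is undefined and reported as NA.

**Bootstrap.** Each pseudoreplicate resamples the characters with
replacement, implemented as re-weighting by the resample counts (weight-0
characters are skipped by the kernels, so this is also the fast path). The
replicate is searched heuristically (default 5 addition sequences — per
replicate exactness is not required for frequency estimation) and
summarized by the strict consensus of the trees it retains: a group counts
only when the replicate recovers it unambiguously, the conservative
convention. The absolute frequency of a group is the percentage of
replicates whose summary contains it; GC subtracts the frequency of its
most frequent contradictory group and is negative when a contradiction
wins. Replicate summaries use the uncollapsed binary trees' consensus;
zero-length-branch collapsing per replicate tree would be the only
difference from the reporting pipeline and changes little when several
co-optimal trees are already intersected.

## The simulation module

`simulate_matrix()` evolves each character from a uniformly drawn root
state down a given tree, changing on each edge with that edge's change
probability: unordered characters jump to a uniformly chosen different
state, ordered characters step &plusmn;1 reflected at the end states.
Homoplasy is thus controlled directly by the knob parsimony cares about —
per-edge change opportunity — rather than through a rate-and-branch-length
model. Missing cells are masked completely at random. The generator
returns the realized number of changes per character, which gives a sharp
test of the fit indices: a realization in which every character's change
count equals its number of distinct tip states minus one is exactly
homoplasy-free, and CI = RI = 1 on the true tree is asserted for such
realizations.

What the generator does **not** emulate: correlated characters,
state-dependent or directional change, missingness concentrated in poorly
preserved taxa, and likelihood-calibrated branch lengths. Tests passing on
this generator therefore validate the algorithms, not the behaviour of any
particular empirical matrix.

`study_template()` emits a 16-taxon &times; 110-character matrix in the
shape of a published archosauriform data set: character 21 ordered, a
0.7/0.2/0.1 mixture of 2-/3-/4-state characters, 20% missing cells (a
typical share for fossil matrices; the knob is exposed), and a per-edge
change probability of 0.07, calibrated so the resulting matrices show an
ensemble CI near 0.6 on their optimal trees — the homoplasy level such
data sets report. It is synthetic data for scale and performance testing,
not a transcription of any published matrix.

**Parameter-recovery experiment.** The recovery check asks the exact
search to return the generating tree as the *unique* optimum. That is only
a fair question when every internal branch carries detectable signal: with
uniform change probabilities an appreciable fraction of internal branches
receive zero changes by chance (at p = 0.05 and 110 characters, roughly 1
in 300 per branch, compounded over 13 internal branches and amplified by
ambiguous placements), and the unique-recovery rate tops out near 80%
for reasons that have nothing to do with the search. The experiment is
therefore designed in the standard "easy zone": internal branches at
change probability 0.05, pendant branches at 0.02, four-state characters,
constant columns redrawn. Under those conditions the suite requires the
generating tree back as the unique optimum in at least 90% of 50
simulations.

## Degenerate inputs, ties, determinism

* All-missing columns normalize to a single placeholder state and score
  zero everywhere; all-constant matrices have &Sigma;s = 0 and CI is
  reported as NA rather than 1.
* Ties in stepwise addition and TBR are broken by branch index, so a seed
  fixes the entire heuristic trajectory; bootstrap tables and study reports
  are byte-identical across runs with the same seed.
* Taxon labels are made newick-safe (spaces to underscores) at
  construction; split bookkeeping is over sorted labels, so row order
  never affects results (asserted in the suite).
* Buffer guards (`max_trees`, `pool_cap`) flag truncation with a warning
  instead of silently dropping trees.

## Problem sizes used by the shipped runs

The test suite validates the exact search against exhaustive enumeration
on 200 random matrices of up to 7 taxa, runs the recovery experiment at 50
seeds of 16 &times; 110, and keeps bootstrap sizes at 40–500 replicates
where only determinism or definitional behaviour is at stake. The
acceptance script analyses the fixture with a 500-replicate bootstrap and
the study-shaped template with 300 replicates, and runs a 20-seed recovery
experiment; binomial sampling error at those sizes (about 1.5–2 percentage
points at p near 0.9) is small against the effects being reported. These
sizes are the package's own reporting choices; all of them are arguments
the user can raise.

## Known limitations

* Exact search is guarded to 20 taxa; the state alphabet is 0–9.
* No step matrices, implied weighting, rescaled consistency index, or
  continuous characters; collapsing rules 2–4 and majority-rule/Adams
  consensus are out of scope.
* GC frequencies depend on the per-replicate summarization convention
  (strict consensus here); other programs' choices can differ by a few
  points at equal B.
* The TNT dialect reader covers `xread` blocks with `ccode +/-//N`
  commands, not the full TNT scripting language.
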