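# cladesearch

Maximum-parsimony analysis of discrete morphological character matrices,
built for the kind of study systematists run when they describe a fossil
taxon and need to place it: a modest matrix (here, tens of taxa by ~100
osteological characters, some ordered, many cells unscorable), an exact
equally-weighted parsimony search, strict consensus of the optimal trees,
ensemble fit indices, and node support from Bremer decay and bootstrap
resampling — the complete workflow, reproducible from a single seed.

## What it computes

For a matrix of characters with per-character weights *w&#7522;*, the length
of a tree is L = Σ *w&#7522;s&#7522;*, where *s&#7522;* is the minimum number
of state changes character *i* needs on that topology — unit cost for
unordered characters (Fitch), |a−b| for ordered/additive characters. The
package provides:

* **Matrix I/O** — TNT `xread` and NEXUS `DATA` dialects, with polymorphic
  cells (`[01]`), missing (`?`) / inapplicable (`-`) entries, ordered-set
  (`ccode +` / `TYPESET ord:`) and weight declarations.
* **Exact search** — branch and bound ("implicit enumeration") over all
  unrooted binary topologies, with admissible per-character and
  character-incompatibility bounds, returning *all* trees within a chosen
  slack of the optimum; optional monophyly constraints
  (`require_monophyly()` / `forbid_monophyly()`).
* **Heuristic search** — random-addition-sequence stepwise trees refined by
  TBR branch swapping, deterministic given a seed.
* **Rule-1 collapse** — contraction of branches whose minimum length over
  all most-parsimonious reconstructions is zero, then deduplication by
  bipartition-set equality.
* **Strict consensus** over the package's own bipartition algebra.
* **Fit statistics** — ensemble consistency index CI = Σm&#7522;/Σs&#7522;
  and retention index RI = (Σg&#7522;−Σs&#7522;)/(Σg&#7522;−Σm&#7522;),
  where m&#7522; is the character's minimum conceivable steps and g&#7522;
  its length on the completely unresolved star tree; both all-characters
  and informative-only variants.
* **Clade support** — Bremer decay index d (optimal length among trees
  lacking the clade minus the optimum; converse-constraint search, with an
  equivalent slack-sweep route), and bootstrap with absolute frequencies
  and GC frequencies (group frequency minus that of its most frequent
  contradictory group; negative when a contradiction wins).
* **Simulation with known truth** — characters evolved on a given tree
  under per-edge change probabilities, so searches, statistics and support
  can all be validated against a generating tree.
* **`reproduce_study()`** — the whole protocol in one call, emitting a
  deterministic JSON/TSV report.

## A worked example

```r
library(cladesearch)

fx <- fixture_small()          # 6 taxa x 10 characters, verified by
print(fx$matrix)               # exhaustive enumeration
#> Character matrix: 6 taxa x 10 characters
#>   ordered characters: 6
#>   missing/inapplicable cells: 2 (3.3%)

rep <- reproduce_study(fx$matrix, config = list(seed = 1, bootstrap_B = 500))
print(rep)
#> Parsimony study: 6 taxa x 10 characters
#>   1 MPT(s) of 14 steps; CI = 0.7857, RI = 0.7500
#>   strict consensus: ((((e,f)1/65/51,d)1/67/53,c)2/86/82,a,b);
#>   clade support (decay / abs% / GC%):
#>     e+f                          1 / 65 / 51
#>     d+e+f                        1 / 67 / 53
#>     c+d+e+f                      2 / 86 / 82
```

Reading: the single most parsimonious tree needs 14 steps; the consistency
index says ~79% of the character change is non-homoplastic; each internal
node is annotated `decay/absolute%/GC%` — e.g. breaking up clade
`c+d+e+f` costs 2 extra steps, and 86% of bootstrap pseudoreplicates
recover it while its best contradictor appears in 4% of them (GC = 82).

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate.R` builds the fixture and a synthetic 16×110
"study-shaped" matrix (character 21 ordered, ~20% missing, homoplasy
calibrated to CI ≈ 0.6), `02_search.R` runs the exact searches and fit
statistics, `03_support.R` the decay/bootstrap support table, and
`04_constrained.R` the constrained-hypothesis costs; outputs land under
`results/`.

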