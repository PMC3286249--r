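---
title: "Maximum parsimony for morphological matrices: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum parsimony for morphological matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moriomorph)
```

## The problem

`moriomorph` performs cladistic analysis of discrete morphological data
under the maximum parsimony criterion: given a taxon-by-character matrix of
integer state codes, find the unrooted tree (or trees) requiring the fewest
character-state changes, and summarize how well the characters fit that
tree.  The package was built around a concrete dataset — the 22-taxon,
75-character matrix for the carabid beetle tribe Moriomorphini (21 ingroup
terminals plus a *Trechus obtusus* outgroup), bundled as a NEXUS file — but
every component works on arbitrary matrices in the supported NEXUS and
TNT-style dialects.

## Characters, costs and cell semantics

Each character is **binary**, **ordered** (additive) or **unordered**
(nonadditive).  A change between states $i$ and $j$ costs $|i - j|$ steps
for ordered characters and one step otherwise; binary characters are stored
as their own kind purely for reporting fidelity, their cost being identical
under both rules.  Ordered characters with gaps in their observed states
keep the full additive cost (states $\{0, 2\}$ are two steps apart).  In
the bundled matrix the ordered/unordered assignment follows the bracket
flags of the published character list; one two-state character (character
4) is flagged additive there and is stored as ordered, which is
cost-equivalent to binary.

Cells may be single states, polymorphic state sets, or missing.  Unknown
(`?`) and inapplicable (`-`) are both mapped to *missing* — fully ambiguous
over the column's states — which is standard parsimony practice; reductive
recoding of inapplicable characters is out of scope.  Polymorphic
terminals are scored as **ambiguity** by default: the leaf may adopt any
of its listed states at no cost.  This matches the convention of the
published TNT run of the bundled matrix ("treated polymorphic terminals as
totally ambiguous").  A **strict** mode is also provided in which a
polymorphic terminal is charged the span of its state set (one step for a
two-state polymorphism) plus the distance from the subtending node — the
Farris-style counting used by Winclada/Nona.  On the bundled matrix each
of the three polymorphic cells costs exactly one extra step on *every*
tree under strict counting, so the two conventions rank all trees
identically there; see "Reproducing the published numbers" below.

## Length computation

Tree lengths are computed by generalized Sankoff dynamic programming over
integer cost matrices, in compiled code, with leaf ambiguity encoded as
per-state leaf cost vectors.  All arithmetic is integer; there is no
floating point anywhere in a length computation, so results are exactly
reproducible.  Because the cost matrices are metrics, the minimum is
independent of root placement; scoring accepts rooted, unrooted, binary
and multifurcating trees.

Two per-character extremes support the fit indices: the **minimum
conceivable steps** $m$ (for unordered characters, the size of a minimal
state set hitting every cell minus one; for ordered characters, the
minimal spanned range over ambiguity resolutions) and the **maximum
steps** $g$, the column's length on the star tree, minimized over the
central state and ambiguity resolutions.

## Fit indices

For observed per-character steps $s_i$ on a tree of length
$L = \sum_i s_i$, the ensemble consistency index is
$\mathrm{CI} = \sum_i m_i / L$ and the ensemble retention index is
$\mathrm{RI} = (\sum_i g_i - L) / (\sum_i g_i - \sum_i m_i)$, with
$\mathrm{RC} = \mathrm{CI} \times \mathrm{RI}$.  `fit_report()` computes
these over all characters *and* restricted to parsimony-informative
characters (those with $g_i > m_i$, the only ones able to show homoplasy
on any tree).  Constant or all-missing characters contribute
$s = m = g = 0$ and are excluded from per-character ratio reporting;
uninformative characters inflate CI, which is why many cladistic programs
report the informative-only variant.  RI is unaffected by that choice,
because uninformative characters have $g_i = m_i$ and cancel from both
numerator and denominator.

## Search

The heuristic search is the classic three-layer recipe:

1. **Random addition.**  Taxa are inserted in RNG-shuffled order, each on
   the edge minimizing incremental length, ties going to the first edge in
   a deterministic enumeration.
2. **Branch swapping.**  First-improvement SPR or TBR, iterated to a local
   optimum.  Both neighborhoods are evaluated incrementally: for each
   bisection the directed Sankoff vectors of the two components are
   computed once, after which every reconnection costs only a profile
   join.  TBR enumerates all reconnection edge pairs; SPR restricts one
   side to its original attachment point, making the SPR neighborhood a
   subset of TBR's.
3. **The parsimony ratchet.**  Each iteration upweights a random fraction
   of characters (default 15% at weight 2), swaps to a local optimum
   under the perturbed weights, restores unit weights, swaps again, and
   accepts the result when no longer than the running best.  The
   published analysis states only the iteration count (200); the
   perturbation fraction and weight default to the mid-range of the
   ratchet method's published recommendation (5–25% upweighting) and are
   exposed in `search_config()`.  The search optimum itself is
   search-strategy independent once reached, so none of these settings
   are tuned to the dataset.

Every source of randomness flows from the single `seed` in
`search_config()`, and all tie-breaking is deterministic, so identical
configurations give bit-identical results.  Every tree returned by
`ratchet_search()` is independently re-scored through `tree_length()`
before the result is released.

Equally optimal trees are deduplicated as unrooted topologies.  Because
counts of most-parsimonious trees depend on how zero-length branches are
treated, the default convention collapses internal edges of *minimum*
length zero (edges on which every character admits a change-free
most-parsimonious reconstruction) before comparing topologies; a flag in
`search_config()` counts uncollapsed binary topologies instead.

`branch_and_bound()` provides an exact oracle for up to 11 taxa: addition
trees are enumerated with pruning on the partial-tree length, which never
decreases as taxa are added.  It returns the complete set of optimal
topologies and is used throughout the test suite to certify the heuristic.

## Ancestral states and apomorphy mapping

`ancestral_states()` reconstructs one most-parsimonious assignment on a
rooted tree by backtracking through the Sankoff vectors in preorder.  Ties
among equally parsimonious child states are broken by policy: ACCTRAN
prefers placing the change on the current edge (accelerating
transformations rootward), DELTRAN prefers retaining the parent's state
(delaying them tipward), and remaining ties go to the lowest state.  Any
such choice realizes the minimum length, which the suite asserts
explicitly.  The published cladogram does not state which convention its
edge annotations used; the package defaults to ACCTRAN and also offers an
"unambiguous-only" mode emitting only changes common to both resolutions.
`map_apomorphies()` diffs parent and child states along every edge; each
record carries the printed 1-based character number and a step count
(`|from - to|` for ordered characters), and step counts sum exactly to the
tree length under either resolution.  A multi-step ordered change is one
record with its full step cost rather than a chain of fictitious unit
records through unobserved intermediate states.

## Reproducing the published numbers

The published analysis of the bundled matrix reports a single tree of
length 301 with CI 0.43 and RI 0.63.  Reproducing those numbers requires
pinning down two reporting conventions the source leaves implicit, and the
package's account is as follows:

* **Length.**  With polymorphic terminals scored as ambiguity — the
  stated convention of the TNT verification run — the optimum of the
  transcribed matrix is **298** steps.  The same optimal topology scores
  **301** under strict (Winclada-style) polymorphism counting, and
  because each of the three polymorphic cells adds exactly one step on
  every tree, the two conventions have identical optimal topologies.
  That constant offset is also the only reading consistent with the
  report that both programs found the same single tree.  The package
  therefore reports the ambiguous-mode optimum (298) as its best length
  and records the polymorphism-aware length (301) of the same topology
  alongside it.
* **CI.**  Neither polymorphism convention yields an all-characters
  ensemble CI rounding to 0.43 (they give 0.44 and 0.45); restricting to
  parsimony-informative characters yields 0.4276 (ambiguous) or 0.4334
  (strict), both rounding to **0.43**.  The published value is therefore
  taken to be the informative-only ensemble, a common reporting
  convention of cladistic software; `fit_report()` always computes both.
* **RI.**  0.6319 under every convention, rounding to **0.63**.

`run_published_analysis()` performs the whole pipeline in one call and writes
tree, fit report, apomorphy table and a manifest recording both length
conventions.

## The simulator

`simulate_tree()` draws Yule, balanced or caterpillar topologies with
exponential(1) branch lengths.  `simulate_characters()` evolves each
character from a uniform root state: unordered characters jump to a
uniformly chosen different state (a k-state Mk-type process), ordered
characters take ±1 steps with reflection at the boundary states, matching
unit-additive cost structure.  Every substitution event is counted, so
parsimony-versus-truth comparisons in the tests are exact: the parsimony
length of a column on its generating tree can never exceed the logged
event count, and at low rates it recovers nearly all events.
`degrade_matrix()` then knocks cells out to missing and expands others to
adjacent-state polymorphisms at configurable rates, emulating the `?`
runs (sex-limited characters) and bracketed polymorphisms of real
morphological tables.

What the simulator deliberately does not model: rate heterogeneity across
lineages, correlated characters, irreversible (Dollo-style) evolution,
and the acquisition biases of real morphological datasets (characters are
typically included *because* they vary).  Passing tests on simulated data
therefore certify the algorithms — scoring, search optimality, index
algebra, mapping — rather than any claim about real-data performance.

## Problem sizes and numerical choices

The test suite certifies the heuristic against branch and bound on
100 simulated 8-taxon/30-character matrices, checks the scorer against
exhaustive internal-assignment enumeration on 500 random trees of up to 7
leaves with missing and polymorphic cells, and measures topology recovery
on 12-taxon matrices of 25/75/225 four-state characters over 20
replicates — sizes chosen so the whole suite certifies every code path
with exact oracles while running comfortably on one CPU.  Cross-checks
against independent implementations (unit-cost lengths versus phangorn's
Fitch routine, Robinson–Foulds distances versus `RF.dist`) guard the
package's own code paths without ever standing in for them.  Lengths,
costs and weights are integers throughout; the only floating-point
quantities in the package are the fit ratios, reported to four decimals
with two-decimal roundings alongside.

## Known limitations

* Inapplicable states are merged with missing; no reductive or
  hierarchical coding of dependent characters.
* No character weighting beyond the ratchet's internal reweighting, no
  implied weights, no user step matrices, and no branch support
  (bootstrap/jackknife/Bremer) — the source analysis reports none.
* `branch_and_bound()` is guarded to 11 taxa; beyond that only the
  heuristic applies.
* TNT-dialect taxon names translate spaces to underscores on writing, so
  names containing literal underscores do not round-trip through that
  dialect.
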