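---
title: "Maximum parsimony for morphological matrices: models, choices, and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum parsimony for morphological matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxpars)
```

## The problem

Palaeontological phylogenetics still runs on discrete morphological
characters: a few dozen taxa scored for on the order of a hundred traits,
with missing cells wherever the fossil does not preserve the structure,
inapplicable codings, and polymorphic cells where a genus shows more than
one condition. The workflow this package implements is the standard one
used, for example, to place the Eocene eagle ray *Promyliobatis gazolai*
among the pelagic stingrays from a 30-taxon × 103-character matrix: find
the most-parsimonious trees (MPTs), summarise them by consensus, quantify
clade support with Bremer decay and character bootstrap, and read the
character-state changes (synapomorphies) off the branches.

maxpars implements each stage as a tested, seedable function, together
with a simulator of morphological matrices with known true trees, so the
entire pipeline can be verified without any external data.

## The optimality criterion

A tree's length is the minimum number of character-state changes needed
to explain the matrix on that topology, summed over characters with their
weights:

\[ L(T) = \sum_i w_i \, s_i(T). \]

Unordered (non-additive) characters are optimised with Fitch state-set
folding: each cell contributes its set of admissible states, intersection
where possible, union (plus one step) where not. Ordered (additive,
Wagner) characters are optimised with Farris intervals, where a change
from state $i$ to $j$ costs $|i - j|$. Both are exact dynamic programs on
a fixed binary tree. The compiled kernel batches all characters per tree;
a plain-R column-wise implementation and an independent Sankoff dynamic
program (which also handles multifurcations) are kept alongside and
cross-checked in the test suite, so the hot path is never the only route
to any number.

Cell semantics, fixed once and used everywhere:

* **Missing (`?`) and inapplicable (`-`)** cells span the full state
  range of their character: they never add steps. The gap symbol is
  remembered only so documents round-trip.
* **Polymorphic cells** such as `(0/1)` are treated as *uncertainty*: an
  ancestor matching any member costs nothing. Under the ordered model a
  polymorphic cell is the interval `[min, max]` of its members. This is
  the cheapest consistent semantics (TNT's default behaviour); it lowers
  step counts relative to treating polymorphism as forced change, which
  is why it is stated here explicitly.

## Homoplasy statistics

With $m_i$ the minimum conceivable steps of character $i$ on *any* tree,
$g_i$ the maximum, and $s_i$ the observed steps, the ensemble consistency
and retention indices are

\[ \mathrm{CI} = \frac{\sum m_i}{\sum s_i}, \qquad
   \mathrm{RI} = \frac{\sum g_i - \sum s_i}{\sum g_i - \sum m_i}. \]

$m_i$ is a minimum hitting-set size over the cell state-sets minus one
(polymorphism resolved in the character's favour); $g_i$ for unordered
characters is the star-tree worst case $n_\mathrm{eff} - \max_s |\{\,
\text{cells admitting } s \,\}|$. For **ordered** characters no closed
form is exact — internal nodes can absorb part of the range, so the
star-tree value overestimates the binary-tree maximum. maxpars finds the
ordered $g_i$ by explicit enumeration over all topologies when at most 8
cells are observed and otherwise reports it as unavailable (ensemble RI
becomes `NA` with a warning). The flagship configuration is fully
unordered, where $G$ is always exact.

Software traditions differ on whether parsimony-uninformative characters
(those with $m_i = g_i$) enter the sums; published CI/RI values rarely
say. Both modes are provided (`include_uninformative`, default `TRUE`),
and reports echo which was used. Reported CI/RI are rounded half-even to
two decimals, matching the precision such values are printed at.

## Tree search

Three searches share one definition of success — return *every* optimal
topology, deduplicated by bipartition set:

* `exhaustive_search()` scores all $(2n-5)!!$ topologies (guarded at 10
  taxa). It exists to be the oracle.
* `branch_and_bound()` is exact at any size in principle: taxa are added
  one at a time and a partial tree is pruned when its length already
  exceeds the incumbent, since adding taxa never removes steps. The
  incumbent starts from a deterministic greedy-addition tree improved by
  TBR. Ties at the optimum are all retained.
* `ras_tbr_search()` is the workhorse beyond ~15 taxa: each replicate
  builds a random stepwise-addition tree (holding `hold` best partial
  trees per step, ties broken first-come in canonical branch order) and
  descends by tree-bisection-reconnection with first-improvement
  acceptance. The globally best trees are then closed under equal-length
  TBR moves (a plateau sweep) so tied MPTs are collected, and the set is
  deduplicated. All randomness flows from one integer seed; equal seeds
  give byte-identical results.

The published protocol this mirrors — 1000 random-addition replicates,
TBR, hold 1, equal weights, unordered — names an exact method and
heuristic parameters in the same breath; maxpars keeps both routes and
records in every report which one ran. The candidate-evaluation loop of
the TBR sweep is compiled, with early abort as soon as a candidate's
partial length reaches the current best; at 30 taxa × 103 characters a
replicate takes on the order of a second, so the full 1000-replicate
protocol is a ten-minute desk computation.

**Collapse rule.** How many "distinct" MPTs a search reports depends on
the rule for collapsing unsupported resolution. maxpars collapses an
internal branch when contracting it leaves the tree length unchanged,
i.e. when some optimal reconstruction places no change on it (the
minimum-length-zero rule). The test is exact, via the Sankoff program on
the contracted (multifurcating) tree. Reports give both the collapsed
and the binary counts; the rule can be disabled.

## Clade support

**Bremer decay** of a clade is the extra length needed before optimal
trees lacking it appear: $\mathrm{bremer}(B) = \min\{L(T) : B \notin T\}
- L_\min$. With few taxa maxpars computes this exactly in one enumeration
sweep. Beyond the guard it runs, per clade, a converse-constraint
RAS+TBR search whose objective penalises any tree containing $B$; a tree
contains $B$ exactly when a synthetic binary character marking $B$ needs
a single step, which is how the constraint is evaluated inside the
kernel. Values above the cap (default 20) are reported censored.

**Character bootstrap** resamples columns with replacement to the
original count, runs a reduced search per pseudoreplicate (10 RAS
replicates, hold 1 — the published protocol does not state per-replicate
settings, so this standard reduction is an explicit assumption), takes
the strict consensus of that replicate's optimal trees (avoiding
arbitrary tie resolution), and reports bipartition frequencies and the
majority-rule tree.

## Synapomorphy mapping

Ancestral states are reconstructed on the outgroup-rooted tree by a
Sankoff traceback that is guaranteed minimal; ACCTRAN prefers a change on
the current edge when costs tie (changes pulled rootward), DELTRAN
prefers keeping the parent's state. For every character, the implied
changes under either convention sum exactly to its step count — this
conservation is asserted in the tests. Changes present under both
conventions (same branch, same states) are flagged `unambiguous`. A
change onto a polymorphic terminal is only reported when no member of the
terminal's state set matches the reconstructed parent state, which the
cost structure produces automatically. Per-character CI
($m_i/s_i$, 1 when $s_i = 0$) is joined to each change, mirroring how
published synapomorphy lists annotate characters.

The outgroup must be chosen by the user; absent a choice, the first
matrix taxon is used with a warning, because polarity is a scientific
decision the software should not make silently.

## The simulator

`simulate_matrix()` evolves each character independently down a random
(or supplied) unrooted topology: uniform root state; along each branch,
with probability `change_prob`, a jump to a uniformly chosen different
state (±1 step in the ordered variant, reflecting at the ends). A
per-branch Bernoulli jump — not a continuous-time Mk process — was chosen
deliberately: it matches parsimony's change-counting view and avoids
entangling rates with branch lengths the target analyses never use; all
branches have length 1. Masking then sets `missing_frac` of cells to `?`
and widens `polymorphic_frac` by one adjacent state, mimicking real
codings like `(0/1)`. `congruent_matrix()` builds homoplasy-free
matrices whose characters each mark one clade; `degrade_to_teeth_taxa()`
reduces chosen taxa to a character subset (default sized 22 of 103, the
coverage of tooth-only fossil stingrays, i.e. about 80% missing),
emulating the instability that tooth-only taxa introduce.

What the simulator does *not* emulate: correlated characters, ordered
state geometries tied to anatomy, non-uniform state frequencies, and
missingness concentrated by body region rather than scattered at random.
Passing tests therefore demonstrate algorithmic correctness and
behaviour under the stated generative model, not fidelity to any
particular empirical matrix.

One empirical property of the generator worth recording: the
tree-recovery rate over `change_prob` is unimodal, not monotone. At very
low change probabilities branches frequently carry *no* marking
character, so the strict consensus is resolution-limited; recovery peaks
at moderate rates and collapses under heavy homoplasy. The tests assert
the defensible ordering (both low rates beat the high rate) rather than
strict monotonicity.

## Verification problem sizes

The acceptance-level checks run at these sizes, chosen to exercise every
code path while staying a desk computation: search-oracle agreement on
100 random matrices of 6–8 taxa × 8–15 characters over 2–3 states;
Fitch/Wagner versus brute-force assignment minimisation on all 4-, 5-
and 6-leaf topologies; Bremer converse-constraint versus enumeration on
6–7-taxon instances; bootstrap with 1000 replicates on a congruent
200-character, 8-taxon matrix; and clade recovery over 100 seeded runs
at 12 taxa × 200 characters with change probability 0.05. A frozen 6×5
fixture (length 8, three MPTs, CI 0.625, RI 4/7) was valued by the
brute-force oracle before the implementations existed.

The published 30 × 103 pelagic-stingray matrix itself is assembled from
several prior studies and is not redistributable here;
`reproduce_published_analysis()` runs the full protocol (and the
documented recoding ledger, `promyliobatis_recodings()`) on a
user-supplied copy and reports the quantities the original analysis
prints: a single MPT of 211 steps, CI 0.65, RI 0.81, Bremer 9/11/1 and
16 synapomorphies on the pelagic-stingray stem.

## Known limitations

* No Sankoff step-matrix characters, implied weighting, ratchet or
  sectorial searches — out of scope for matrices of this size.
* Ordered-character ensemble RI is exact only while every ordered
  character has ≤ 8 observed cells (enumeration guard).
* Heuristic Bremer values are lower-bounded searches; the cap and the
  censoring flag make that explicit.
* The NEXUS reader covers the morphological-data dialect (CHARACTERS /
  DATA, FORMAT, MATRIX, TYPESET/WTSET assumptions), not the full grammar.
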