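---
title: "Exact combinatorics of spinal phylogenetic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact combinatorics of spinal phylogenetic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinalnets)
```

## The objects

A rooted phylogenetic network on `n` leaves is a directed acyclic graph with
one in-degree-0 vertex (the root), `n` out-degree-0 vertices of in-degree 1
(the leaves, labelled `1..n`), and internal vertices of arbitrary in- and
out-degree at least 1. Vertices of in-degree two or more are *reticulations*
and model hybridisation or horizontal transfer; vertices of in-degree at
most one are *tree vertices*. A network is *spinal* when a single directed
path from the root to a leaf passes through every non-leaf vertex — the
network analogue of a caterpillar tree, and for the same reasons an extreme
case: among all networks with a fixed number of non-leaf vertices the spinal
ones are exactly those of maximal height, so they bound height-dependent
algorithms and balance indices, and rapidly evolving clades (e.g. seasonal
viral pathogens) tend towards this shape.

Knowing how many networks lie in a class matters beyond curiosity: MCMC and
other samplers over network space need the size of the support to set
priors, and judging whether spine-like histories are over-represented in
real data requires the size of the spinal class within a larger one.

## Expanding covers and the labelling algorithm

The package's first encoding applies to *labellable* networks. With leaves
labelled `1..n`, the labelling algorithm repeatedly picks, among the
unlabelled non-root vertices whose children are all labelled, the one whose
children-label set is least, and assigns it the next label `n+1, n+2, ...`.
A network is labellable when this choice is unique at every step
(`label_vertices()` reports `not_labellable` otherwise, e.g. when two
vertices share an identical children set).

The order used is lexicographic on label sets read as ascending sequences,
with a proper prefix ordered first: `{1,5}` precedes `{5}` (smaller first
element) and `{1}` precedes `{1,5}` (prefix). One published phrasing of this
order ("A before B if A ⊆ B or the minimum of the symmetric difference lies
in A") is self-contradictory for subset pairs that are not prefixes —
applied literally it puts `{5}` both before and after `{1,5}` — but the
worked labellings accompanying it fix the intent, and `spinalnets`
implements exactly that sequence order.

Collecting the children-label set of each non-leaf vertex, in label order
with the root's set last, yields the network's *expanding cover*: a
collection of `c` subsets of `{1..m}` (with `m` the number of non-root
vertices and `n = m - c + 1`) in which no leaf element is repeated and, for
every `i`, at least `i` sets lie inside `{1..n+i-1}`. This is a bijection:
`cover_to_network()` and `network_to_cover()` invert each other, which the
test suite verifies on every expanding cover of small ground sets.

```{r covers}
cov <- parse_cover("{2,3};{1,5};{5};{4,7};{5,6};{5,7,9};{8,10}")
cov
validate_expanding(cov)$is_expanding
is_spinal_cover(cov)   # this one is labellable but not spinal
```

Spinal networks are exactly those whose cover has *exactly* `i` subsets of
`{1..n+i-1}` for every `i`; equivalently, from the second set on, set `i`
contains `n+i-1`. Further cover conditions characterise tree-child
(`is_tree_child_cover()`: every set holds a uniquely occurring element),
non-degenerate and binary networks (`is_nondegenerate_cover()`,
`is_binary_cover()`); the binary test additionally requires the root's set
to have size two, since a binary root must have out-degree two — a
condition easy to lose when reading the per-position multiplicity rules,
whose clause for the root position is vacuous (`n+c` exceeds the ground
set).

## LRP sequences: canonical words for binary spinal shapes

For *binary* spinal networks the package uses a second, tighter encoding.
Walking the spine from its leaf end to the root, every non-leaf vertex
carries exactly one arc off the spinal path: to a leaf (`L`), from a later
spine vertex (it is the `i`-th reticulation, `R_i`), or to an earlier one
(it is the non-spinal parent of reticulation `i`, `P_i`). The resulting
word over `{L, R_1..R_k, P_1..P_k}` has `n-1` `L`s and length `n+2k-1`, and
is a *canonical form*: by spine uniqueness, two binary spinal shapes are
isomorphic iff their LRP sequences are equal, so no graph-isomorphism
machinery is needed anywhere in the package.

Order rules delimit classes (`check_rules()`, `class_spec()`):

| rule | reading | classes |
|------|---------|---------|
| R1 | `R_j` after `R_i` for `j > i` | all |
| R2 | `P_i` after `R_i` | all |
| R3 | `P_i` not immediately after `R_i` (no parallel arc) | all but the parallel-arc class |
| R4a | `R_i` immediately followed by `L` | tree-child |
| R4b | `R_i` not immediately followed by an `R_j` | stack-free |
| R4c | `R_i` not immediately followed by a `P_j` | fully tree-sibling |

`decode_lrp()` rebuilds the shape and `encode_lrp()` recovers the word; the
suite checks they are mutually inverse on every shape with `n + 2k <= 9`,
and that each rule verdict coincides with the corresponding graph-level
predicate of `classify_network()`. For that equivalence to hold in the
parallel-arc class the sibling relation must respect arc multiplicity: under
a parallel arc a reticulation is its own sibling, which is precisely why an
`R_iP_i` adjacency breaks the fully-tree-sibling rule.

```{r lrp}
s <- parse_lrp("R1,L,P1,R2,L,P2,L")
classify_network(decode_lrp(s))[c("binary", "spinal", "tree_child")]
```

## Three bijections, three counting formulas

Valid sequences split into blocks whose arrangement is counted by classical
families, giving exact shape counts (all arithmetic is exact and
arbitrary-precision; see below):

* **Tree-child**: blocks `R_iL`, `L`, `P_i`; pairing each `R_iL` position
  with its `P_i` position yields a partition of `{1..n-1+k}` into `k`
  doubletons and `n-1-k` singletons — Bessel numbers,
  `bessel_shapes(n, k) = (n-1+k)!/(2^k (n-1-k)! k!)`
  (`lrp_to_bessel_partition()`).
* **Stack-free**: blocks `R_iL`, `R_iP_j`, `L`, `P_i`; relating each `R_i`
  block to the block holding `P_i` and closing transitively partitions
  `{1..n-1+k}` into exactly `n-1` parts — Stirling numbers of the second
  kind (`lrp_to_set_partition()`).
* **Fully tree-sibling**: blocks `R_i..R_hL`, `L`, `P_i`; each run block and
  its parents form a cycle — permutations of `{1..n-1+k}` with `n-1`
  cycles, unsigned Stirling numbers of the first kind
  (`lrp_to_permutation()`).

Shapes become leaf-labelled networks through the cherry lemma
(`shapes_to_networks()`): a class closed under leaf permutation, cherry
reduction and re-cherrying has
`n! * shapes(n,k) - (n!/2) * shapes(n-1,k)` networks, because a shape with a
cherry (equivalently, whose LRP sequence begins with `L`; such shapes
biject with `(n-1)`-leaf shapes by cherry reduction, `cherry_reduce()` /
`recherry()`) admits only `n!/2` distinct labellings.

Two further classes round out the picture. Allowing parallel arcs, a shape
is just a choice of `k` disjoint position pairs on the spine, giving
`count_bsp()`; forbidding parallel arcs removes adjacent pairs and is
handled by the three-term recursion of `count_bss_shapes()`, classified by
what the spine vertex nearest the root does. The all-spinal class (no
binarity restriction) is counted directly on covers by `count_spinal(n, c)
= 2^C(c-1,2) (c^n - (c-1)^n)`, indexed by cover size rather than
reticulation number.

Wherever a count has two published forms, both are evaluated on every call
and a disagreement raises an internal error rather than silently choosing
one (`count_stc()`, `count_ssf()`, `count_bsp()`, `stirling2()`).

```{r counts}
count_stc(4, 2); count_ssf(4, 2); count_fts(4, 2); count_bs(4, 2); count_bsp(4, 2)
class_table("stc", 1:4, 0:3, total = TRUE)
```

## Oracles: why the formulas can be believed

Every formula is tested against machinery that shares nothing with it:

* `enumerate_lrp()` backtracks over letters under a rule set; its stream
  length must equal the class's shape formula for all `n + 2k <= 9`.
* `brute_force_covers()` enumerates *all* collections of `c` distinct
  non-empty subsets of `{1..m}` as bitmasks (sorted by mask, which refines
  the order by maximum, so the expanding condition prunes exactly) and
  filters by definition; filtered spinally it must match both the
  constructive generator `enumerate_spinal_covers()` and `count_spinal()`
  for `n + c <= 8`.
* `enumerate_networks()` expands shapes through explicit leaf labellings
  with the cherry correction and must match the network-count formulas.

The test suite runs these sweeps at the sizes above; they complete in well
under a minute in total. Sizes were chosen so each sweep still covers every
structural case (cherry/non-cherry shapes, all rule interactions, spinal
and non-spinal, degenerate and binary covers) while staying desk-scale.

## Exact integers

Counts in this domain exceed 2^53 already at single-digit parameters (the
largest table entries run to 10^28), so every counting function returns a
`bigint`, a small exact sign-and-magnitude integer type included in the
package (base-10^6 digit vectors with schoolbook arithmetic, `Ops` methods,
and exact division). Division by factorials and powers of two is routed
through prime factorisation so that each intermediate division step is
exact; `big_div_small()` errors on any non-exact quotient rather than
truncating. Binomials are built by the multiplicative formula, whose
stepwise divisions are always exact. No floating point enters any count.

## Uniform sampling

`sample_network(class, n, k, seed)` draws uniformly over the leaf-labelled
networks of a class by drawing a *shape* uniformly from the bijection
target family — pairings for tree-child and the parallel-arc class
(rejecting adjacent pairs for the no-parallel class), set partitions with
`n-1` parts for stack-free, permutations with `n-1` cycles for fully
tree-sibling, each by standard recurrence-weighted constructions — then a
uniform leaf labelling, accepting cherry-shape draws with probability 1/2
after canonicalising the cherry pair. That acceptance step exactly
compensates the two interchangeable cherry labellings, so all networks in
the class receive equal mass. The RNG is R's global generator, seeded once
per call when `seed` is supplied; identical seeds give byte-identical
output. The suite checks draw frequencies against the exhaustive class list
with a chi-square statistic at the 0.999 quantile.

## Design notes and limitations

* *Root conventions.* "Internal vertices" means non-root non-leaf
  throughout; a binary `(n, k)` network has `n + 2k - 2` of them, and its
  spine has `n + 2k - 1` non-leaf vertices once the root is included. The
  root's cover set is exempt from the multiplicity clauses of the
  degeneracy/binarity characterisations (label `n+c` does not exist) but
  must have size two for binarity.
* *Degenerate inputs.* Out-of-domain counting parameters (`k < 0`, `n = 0`,
  `k >= n` for tree-child) return 0 so that table generation is total; the
  single-leaf column is handled without a cherry correction (there is no
  0-leaf shape). The one-leaf, one-reticulation class without parallel arcs
  is empty — the only zero in its tables — and the samplers refuse empty
  classes.
* *Two sets in a cover are never equal*: equal children sets make the
  labelling algorithm non-deterministic, so construction rejects them.
* *Canonical choices.* The spine's starting leaf is the smaller admissible
  label; enumeration streams are emitted in lexicographic letter order;
  eNewick hybrid tags are numbered along the spine. All are conventions of
  this package, chosen for reproducible output, not properties of the
  mathematics.
* *Scope.* The spinal class with parallel arcs and no binarity bound is
  infinite for every `(n, k)` and is refused by the counting and
  enumeration surfaces with an explanatory error. Non-labellable networks
  have no cover and are out of scope except for detection; consequently the
  maximal-height property is verified over *labellable* binary networks,
  which is where the cover-based enumeration can reach.
* *What the tests do not show.* All verification is exhaustive at small
  sizes plus formula identities at moderate sizes; nothing here validates
  against empirical phylogenies, and the samplers model no evolutionary
  process — they are uniform measures on combinatorial classes, intended
  for prior calibration and algorithm testing.
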