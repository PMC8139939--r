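---
title: "Universal tree sets and the incompatibility of split systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Universal tree sets and the incompatibility of split systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitcover)
```

## The model

An unrooted phylogenetic tree on a taxa set $X$ ($|X| = n \ge 2$, no
degree-2 vertices, leaves bijectively labelled) is equivalent to the set of
bipartitions ("splits") induced by deleting each of its edges. A split
$A|B$ has size $\min(|A|,|B|)$; size-1 splits are *trivial* and are displayed
by every tree (they are the leaf edges). Two splits $A|B$ and $C|D$ can sit
in one tree exactly when at least one of $A\cap C$, $A\cap D$, $B\cap C$,
$B\cap D$ is empty (Buneman's condition), and a split system containing all
trivial splits corresponds to a tree precisely when it is pairwise
compatible — the splits equivalence theorem, which this package exercises in
both directions (`splits_of_tree()`, `tree_from_splits()`).

Real data (gene-by-gene signal, lateral transfer, incomplete lineage
sorting) frequently produce split systems that no single tree displays.
`splitcover` quantifies how far such a system $S$ is from tree-like by

* $\kappa(S)$, the **minimal tree set size**: the least number of trees whose
  displayed splits cover $S$ (`min_tree_set()`);
* the **k-compatibility level**: the largest subset of mutually
  incompatible splits (`max_incompatible_subset_size()`);
* $U(n)$, the **universal incompatibility**: $\kappa$ of the full split set
  $\mathcal{S}(X)$, i.e. the worst case on $n$ taxa (`universal_size()`,
  `build_universal_tree_set()`);
* $\mathrm{Norm}(S) = \kappa(S)/U(n)$, which makes incompatibility
  comparable across taxon counts (`normalized_tree_set_size()`,
  `norm_ratio()`).

Since trivial splits are free, $\kappa$ equals the minimum number of
pairwise-compatible classes partitioning the nontrivial splits of $S$ —
the chromatic number of the *incompatibility graph* (one vertex per
nontrivial split, edges between incompatible pairs). The clique number of
the same graph is the k-compatibility level. The two invariants genuinely
differ: for the five-split system
$\{12|345,\,23|145,\,34|125,\,45|123,\,15|234\}$ the incompatibility graph
is a 5-cycle, whose clique number is 2 but whose chromatic number is 3:

```{r example-cycle}
S <- split_system(list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5)), taxa_set(5))
max_incompatible_subset_size(S)
min_tree_set(S)
```

## The closed form for U(n) and its construction

Write $m = \lfloor n/2 \rfloor$. A tree on $n$ taxa displays at most one
split of size $m$ when $n$ is even and at most two when $n$ is odd, so with
$\binom{n}{m}$ such splits (counting each bipartition once for even $n$
gives $\tfrac12\binom{n}{m}$),

$$U(n) = \left\lceil \tfrac12 \binom{n}{m} \right\rceil \quad (n \ge 4),$$

and `build_universal_tree_set()` attains the bound constructively:

1. **Symmetric chain decomposition.** The non-empty subsets of size
   $\le m$ are partitioned into $\binom{n}{m}$ inclusion chains with
   consecutive sizes, one size-$m$ subset per chain
   (`symmetric_chain_decomposition()`). Existence follows from the
   Sperner/Dilworth count; we fix the bracket-matching construction
   (element present = opening bracket; a chain freezes the matched
   positions and grows through the unmatched ones) so the output is
   deterministic in the taxa order. The constructor re-verifies every
   invariant at run time.
2. **Chains to splits.** $\gamma: A \mapsto A|(X\setminus A)$ maps each
   chain to a nested — hence pairwise compatible — family of splits.
3. **Pairing the maximum-size splits.** For even $n$ the two chains
   carrying complementary size-$m$ subsets map to the same split and are
   merged. For odd $n$ the compatibility graph of the size-$m$ splits
   (`bip_compatibility_graph()`) is connected, $(m{+}1)$-regular and
   vertex-transitive, so it has a perfect matching when $\binom{n}{m}$ is
   even and a defect-1 matching when it is odd — by Kummer's theorem
   (`carries()`), $\binom{2m+1}{m}$ is odd exactly when $n = 2^k - 1$
   (`central_binomial_is_odd()`). We do not re-derive the matching
   existence proof; `max_matching()` runs a general blossom maximum-matching
   algorithm (in C++) and asserts that the defect equals the predicted 0
   or 1, turning the theorem into an executable check. Matched chains are
   merged; for $n = 2^k - 1$ one chain stays alone, which is the ceiling
   in the formula.
4. **Classes to trees.** Each merged class is pairwise compatible (this is
   re-verified, not assumed) and `tree_from_splits()` turns it into one
   tree.

For $n \in \{2, 3\}$ every split is trivial and the star tree alone is
universal, so $U(2) = U(3) = 1$. We implement this special case rather than
the $n \ge 4$ formula (which would give 2 at $n = 3$): the capacity argument
behind the formula concerns nontrivial splits and there are none.

```{r construct}
ts <- build_universal_tree_set(6)
length(ts)                      # U(6) = 10
displays(ts, all_splits(6))
```

## The exact kappa solver

`min_tree_set()` computes the chromatic number of the incompatibility graph
exactly:

* upper bound: greedy colouring, largest incompatibility degree first;
* lower bounds: the exact clique number (via igraph's branch-and-bound)
  and the per-tree capacities (`capacity_lower_bound()`): at most
  $n-3$ nontrivial splits per tree, and at most one (even $n$) or two
  (odd $n$) splits of size $m$;
* iterative deepening from the lower bound with a DSATUR-ordered exact
  search; symmetry is broken by allowing each branch to open at most one
  new class.

The search is deterministic: vertices are held in the canonical split
order (by side size, then lexicographically), with no randomisation, so
results are bit-for-bit reproducible. The default node budget is unlimited
for up to 25 nontrivial splits and $2\times10^5$ search nodes beyond that;
on exhaustion the solver returns the best partition found with
`optimal = FALSE` and honest `lower_bound`/`upper_bound` — it never
mislabels a heuristic answer as exact, and `normalized_tree_set_size()`
refuses non-certified values unless explicitly overridden. A tree in a
minimal set may display splits outside $S$; only coverage of $S$ is
required, and each class tree carries exactly its class plus the trivial
splits.

Conventions for degenerate inputs: a non-empty all-trivial system has
$\kappa = 1$ (the star tree); the empty system has $\kappa = 0$ by
convention (the textbook definition starts at $k \ge 1$; a solver should
not need a tree to cover nothing). Split weights, where present in input
files, are parsed and carried but ignored by $\kappa$ and Norm —
incompatibility is weight-agnostic here.

## Building trees from compatible splits

The user-facing contract is the splits equivalence theorem; our
implementation exploits the canonical representation. Every split is stored
by its side not containing taxon 1. For two such sides, Buneman
compatibility collapses to "nested or disjoint", so a pairwise-compatible
class is a laminar family and its nesting forest *is* the tree, rooted at
the interior vertex on taxon 1's side of every split. This replaces
iterative edge refinement ("tree popping") with a single recursive
construction; the output is identical (the theorem's tree is unique up to
isomorphism) and deterministic, with children ordered by smallest taxon
index. The same canonicalization makes split equality, hashing and
deduplication unambiguous — `make_split(A)` and `make_split(X \ A)` are one
object.

## File formats

Newick I/O is delegated to `ape` (`read_newick()`, `write_newick()`); trees
are written without branch lengths, and a degree-2 root is suppressed on
input so round trips preserve split systems exactly. The SplitsTree-style
NEXUS `SPLITS` reader is written here because we want strict validation
(sides must be non-empty proper subsets; every error names its line) and
tolerance for the st_splits dialect (bracketed comments, trailing commas,
`CYCLE`, quoted labels, `labels=left` id columns); `phangorn`'s independent
SPLITS writer is used as a cross-check in the tests. A plain one-split-per-
line text format (`read_split_list()`) covers hand-written systems.

## The synthetic generator

`generate_split_system(n, n_trees, extra_incompatible, seed)` emulates the
situation the solver is built for: a shared backbone signal distributed over
a few trees plus unstructured conflict. It grows `n_trees` random binary
trees by sequential leaf attachment (each new leaf subdivides a uniformly
chosen edge — not the uniform distribution over topologies, which is
irrelevant for fixtures and documented), unions their nontrivial splits
(hence $\kappa \le$ `n_trees` by construction, which the tests verify), and
adds uniformly sampled extra nontrivial splits. Everything is seeded through
an isolated RNG scope, so identical parameters give byte-identical files.
What the generator does **not** emulate: split weights, the geometry of
Neighbor-Net cycles, and correlated conflict such as a single recombination
breakpoint — passing tests say nothing about those aspects of real data.

## Problem sizes and numerical choices

All quantities here are small integers and exact; there is no floating-point
tolerance anywhere ($U(n)$ up to $n \approx 30$ stays far below the double
integer limit). The test suite sizes were chosen to keep exhaustive oracles
honest but fast: brute-force partition minima referee the solver on systems
with at most 8 nontrivial splits (200 seeds); compatibility is checked
against the literal four-intersection definition exhaustively for
$n \le 7$; universal tree sets are built and verified for $n \le 12$
(462 trees, 2047 splits); matchings are checked for
$n \in \{5,7,9,11,13,15\}$ — the $n = 15$ graph has 6435 vertices and runs
in seconds thanks to the C++ matching kernel and the disjointness-based
edge enumeration.

## Limitations

* The exact solver targets the scale of published split networks (tens of
  nontrivial splits); it is not an approximation scheme for huge systems.
* Only the `TAXA` and `SPLITS` NEXUS blocks are parsed; `NETWORK` blocks,
  distance matrices and Neighbor-Net reconstruction are out of scope.
* Weighted or weight-thresholded variants of $\kappa$ are not provided.
* Duplicate trees in a tree set are allowed (they never help minimality).
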