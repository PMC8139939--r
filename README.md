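# splitcover

Phylogenetic data rarely agree on a single tree: gene-by-gene signal,
lateral gene transfer or incomplete lineage sorting produce *split systems*
(sets of bipartitions of the taxa) that no one tree can display, the kind of
conflict that SplitsTree renders as a split network. `splitcover` is for
researchers who want to put an exact number on that conflict and compare it
fairly across datasets with different numbers of taxa.

The quantities it computes, for a split system *S* on *n* taxa:

* **κ(S)** — the *minimal tree set size*: the least number of unrooted trees
  whose displayed splits cover *S*. Because trivial splits are displayed by
  every tree, κ equals the minimum number of pairwise-compatible (Buneman)
  classes partitioning the nontrivial splits — the chromatic number of the
  incompatibility graph — and is computed exactly (`min_tree_set()`).
* **k-compatibility** — the largest pairwise-incompatible subset of *S*, the
  clique number of the same graph (`max_incompatible_subset_size()`). It
  lower-bounds κ but is not equal to it.
* **U(n)** — the *universal incompatibility*: κ of the full split set, i.e.
  the worst case on *n* taxa. For m = ⌊n/2⌋,

  U(n) = ⌈ C(n, m) / 2 ⌉ for n ≥ 4, and U(2) = U(3) = 1.

  `universal_size()` evaluates the closed form;
  `build_universal_tree_set()` constructs a witness of exactly that size
  (symmetric chain decomposition of the subset lattice + blossom maximum
  matching on the compatibility graph of the size-m splits) and verifies it.
* **Norm(S) = κ(S)/U(n)** — the normalized tree set size, an exact fraction
  comparable across taxon counts (`normalized_tree_set_size()`,
  `norm_ratio()`).

Split systems come from SplitsTree-style NEXUS `SPLITS` files
(`read_nexus_splits()`), Newick trees (`read_newick()`), plain split lists
(`read_split_list()`), or the seeded synthetic generator
(`generate_split_system()`).

## Worked example

The five-split system S = {12|345, 23|145, 34|125, 45|123, 15|234} on taxa
{1..5} (shipped as `inst/extdata/example21.nex`) is 2-compatible — no three
splits are mutually incompatible — yet needs three trees:

```r
library(splitcover)
S <- split_system(list(c(1,2), c(2,3), c(3,4), c(4,5), c(1,5)), taxa_set(5))
min_tree_set(S)
#> Minimal tree set: k = 3 (optimal) on 5 taxa
#>   5 split(s), 5 nontrivial; clique bound 2, capacity bound 3
```

`k = 3` is κ(S), certified optimal; the `clique bound 2` line is the
k-compatibility level (two mutually incompatible splits exist, never
three); the `capacity bound 3` is what forces a third tree — a 5-leaf tree
displays at most two size-2 splits and S contains five. The three trees:

```r
for (tr in min_tree_set(S)$trees) cat(ape::write.tree(tr), "\n")
#> (1,(2,3),(4,5));
#> (1,(2,(3,4)),5);
#> (1,2,(3,4,5));
norm_ratio(3, 5)
#> 3/5 (= 0.6)
```

The same numbers from the shell, via the bundled CLI (`exec/splitcover`):

```sh
splitcover kappa example21.nex --exact --json -
splitcover usize 13          # 858
splitcover construct 6 -o u6.nwk && splitcover verify-universal u6.nwk -n 6
```

Normalization is what makes cross-size comparisons meaningful: a 13-taxon
network with κ = 4 is *less* incompatible relative to its worst case than a
12-taxon network with κ = 3, since `norm_ratio(4, 13) < norm_ratio(3, 12)`
(4/858 < 3/462).

See `vignettes/universal-tree-sets.Rmd` for the model, the constructive
proof the builder follows, solver internals and limitations.

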