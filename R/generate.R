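#' Deterministic synthetic split systems
#'
#' Builds `n_trees` random binary trees by seeded sequential leaf attachment
#' (each new leaf subdivides a uniformly chosen edge; not uniform over
#' topologies), takes the union of their nontrivial splits — so the minimal
#' tree set size is at most `n_trees` by construction — and then adds up to
#' `extra_incompatible` further splits sampled uniformly from the splits of
#' size >= 2 not already present. Fully reproducible from
#' `(n, n_trees, extra_incompatible, seed)`.
#'
#' @param n Number of taxa, `>= 4`.
#' @param n_trees Number of source trees, `>= 1`.
#' @param extra_incompatible Number of additional random splits, `>= 0`.
#' @param seed Integer seed.
#' @return A `"split_system"` on the taxa `"1"..."n"`.
#' @examples
#' S <- generate_split_system(6, 2, 3, seed = 42)
#' min_tree_set(S)$k
#' @export
generate_split_system <- function(n, n_trees = 1L, extra_incompatible = 0L,
                                  seed = 1L) {
  stopifnot(n >= 4, n == round(n), n_trees >= 1, extra_incompatible >= 0)
  n <- as.integer(n)
  labels <- taxa_set(n)
  withr::with_seed(as.integer(seed), {
    sides <- unlist(lapply(seq_len(n_trees), function(i) {
      random_tree_sides(n)
    }), recursive = FALSE)
    have <- unique(vapply(sides, side_key, ""))
    added <- 0L
    attempts <- 0L
    while (added < extra_incompatible && attempts < 200L * (extra_incompatible + 1L)) {
      attempts <- attempts + 1L
      sz <- sample(2:(n - 2L), 1L)
      side <- canonical_side(sample.int(n, sz), n)
      key <- side_key(side)
      if (!key %in% have) {
        have <- c(have, key)
        sides <- c(sides, list(side))
        added <- added + 1L
      }
    }
    new_split_system(sides, labels)
  })
}

#' Random binary tree by sequential leaf attachment
#'
#' Starts from the three-leaf star and attaches leaves `4..n` in order, each
#' to a uniformly chosen existing edge. Used by [generate_split_system()];
#' exported for building test fixtures.
#'
#' @param n Number of leaves, `>= 3`.
#' @param taxa Optional taxa set (defaults to `"1"..."n"`).
#' @return A `phylo` object. Note: draws from the current RNG stream; seed it
#'   (or use [generate_split_system()]) for reproducibility.
#' @export
random_attachment_tree <- function(n, taxa = NULL) {
  stopifnot(n >= 3, n == round(n))
  n <- as.integer(n)
  labels <- if (is.null(taxa)) taxa_set(n) else taxa_set(taxa)
  stopifnot(length(labels) == n)
  sides <- random_tree_sides(n)
  tree_from_splits(new_split_system(c(sides, as.list(seq_len(n))), labels))
}

# nontrivial canonical sides of a random sequential-attachment binary tree
random_tree_sides <- function(n) {
  # edge list over node ids: leaves 1..n, internal ids n+1, n+2, ...
  from <- c(n + 1L, n + 1L, n + 1L)
  to <- c(1L, 2L, 3L)
  next_id <- n + 2L
  if (n >= 4L) for (leaf in seq.int(4L, n)) {
    e <- sample.int(length(from), 1L)
    v <- next_id
    next_id <- next_id + 1L
    old_to <- to[e]
    to[e] <- v
    from <- c(from, v, v)
    to <- c(to, old_to, leaf)
  }
  # one split per internal edge: leaves reachable from `to` without the edge
  n_nodes <- next_id - 1L
  adj <- vector("list", n_nodes)
  for (i in seq_along(from)) {
    adj[[from[i]]] <- c(adj[[from[i]]], to[i])
    adj[[to[i]]] <- c(adj[[to[i]]], from[i])
  }
  sides <- list()
  for (i in seq_along(from)) {
    if (to[i] <= n) next  # leaf edge -> trivial split
    part <- leaves_beyond(adj, block = from[i], start = to[i], n = n)
    if (length(part) >= 2L && length(part) <= n - 2L) {
      sides <- c(sides, list(canonical_side(part, n)))
    }
  }
  sides
}

leaves_beyond <- function(adj, block, start, n) {
  seen <- c(block, start)
  stack <- start
  leaves <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= n) leaves <- c(leaves, v)
    nb <- setdiff(adj[[v]], seen)
    seen <- c(seen, nb)
    stack <- c(stack, nb)
  }
  sort(leaves)
}
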