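# Independent oracles and fixture builders. The oracles deliberately avoid the
# package's internal representations: they work on plain label sets and use
# brute-force enumeration, so they can referee the fast implementations.

# literal four-intersection compatibility test on label sets
oracle_compatible <- function(a_labels, all_labels) {
  function(b_labels) {
    A <- a_labels; B <- setdiff(all_labels, a_labels)
    C <- b_labels; D <- setdiff(all_labels, b_labels)
    length(intersect(A, C)) == 0 || length(intersect(A, D)) == 0 ||
      length(intersect(B, C)) == 0 || length(intersect(B, D)) == 0
  }
}

split_labels <- function(s) s$labels[s$side]

oracle_pair_compatible <- function(s1, s2) {
  oracle_compatible(split_labels(s1), s1$labels)(split_labels(s2))
}

# maximum pairwise-incompatible subset by enumeration of all subsets
oracle_max_incompatible <- function(S) {
  sp <- system_splits(S, nontrivial = TRUE)
  v <- length(sp)
  if (v == 0) return(0L)
  best <- 1L
  for (size in seq.int(2L, v)) {
    for (idx in combn_idx(v, size)) {
      ok <- TRUE
      for (i in seq_len(size - 1L)) {
        for (j in seq.int(i + 1L, size)) {
          if (oracle_pair_compatible(sp[[idx[i]]], sp[[idx[j]]])) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (ok) {
        best <- size
        break
      }
    }
  }
  best
}

combn_idx <- function(v, k) {
  if (v == 1) return(if (k == 1) list(1L) else list())
  utils::combn(v, k, simplify = FALSE)
}

# exact minimum number of pairwise-compatible classes by recursive partition
# search: place each split into an existing compatible class or a new one
oracle_min_partition <- function(S) {
  sp <- system_splits(S, nontrivial = TRUE)
  v <- length(sp)
  if (v == 0) return(as.integer(n_splits(S) > 0))
  best <- v
  recurse <- function(i, classes) {
    if (length(classes) >= best) return()
    if (i > v) {
      best <<- length(classes)
      return()
    }
    for (c0 in seq_along(classes)) {
      if (all(vapply(classes[[c0]], function(j) {
        oracle_pair_compatible(sp[[j]], sp[[i]])
      }, NA))) {
        classes[[c0]] <- c(classes[[c0]], i)
        recurse(i + 1L, classes)
        classes[[c0]] <- classes[[c0]][-length(classes[[c0]])]
      }
    }
    recurse(i + 1L, c(classes, list(i)))
  }
  recurse(1L, list())
  best
}

# exponent of prime p in choose(a + b, a), via Legendre's factorial valuation
oracle_padic_valuation_binom <- function(a, b, p) {
  legendre <- function(x) {
    tot <- 0
    pk <- p
    while (pk <= x) {
      tot <- tot + x %/% pk
      pk <- pk * p
    }
    tot
  }
  legendre(a + b) - legendre(a) - legendre(b)
}

# the five-split system from the five-cycle worked example on taxa 1..5
example_cycle_system <- function() {
  split_system(list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5)), taxa_set(5))
}

# a random pairwise-compatible system: the nontrivial splits of one random tree
random_compatible_system <- function(n, seed) {
  generate_split_system(n, n_trees = 1L, extra_incompatible = 0L, seed = seed)
}
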