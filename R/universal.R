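#' Universal incompatibility U(n)
#'
#' The minimal size of a universal tree set — a set of trees that together
#' display all `2^(n-1) - 1` splits on `n` taxa. For `n >= 4`,
#' `U(n) = ceiling(choose(n, floor(n/2)) / 2)`: a tree displays at most one
#' split of maximum size `m = n/2` when `n` is even, and at most two when `n`
#' is odd, and the constructive bound is attained. For `n = 2` and `n = 3`
#' every split is trivial, so the star tree alone displays all of them and
#' `U(n) = 1`.
#'
#' @param n Number of taxa, an integer `>= 2`.
#' @return The universal tree set size, as a number.
#' @examples
#' universal_size(5)   # 5
#' universal_size(13)  # 858
#' sapply(4:9, universal_size)  # 3 5 10 18 35 63
#' @export
universal_size <- function(n) {
  if (length(n) != 1L || is.na(n) || n != round(n)) {
    stop("n must be a single integer")
  }
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  if (n <= 3L) return(1)
  ceiling(choose(n, n %/% 2L) / 2)
}

is_prime <- function(p) {
  if (p < 2L) return(FALSE)
  if (p < 4L) return(TRUE)
  if (p %% 2L == 0L) return(FALSE)
  d <- 3
  while (d * d <= p) {
    if (p %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}

#' Number of carries when adding two integers in base p
#'
#' Runs the digit recurrence from the least significant digit: a carry occurs
#' at digit i when the two digits plus the incoming carry reach `p`. By
#' Kummer's theorem the result equals the exponent of the prime `p` in
#' `choose(a + b, a)`.
#'
#' @param a,b Positive integers.
#' @param p A prime base.
#' @return The non-negative number of carries.
#' @examples
#' carries(15, 4, 2)  # 2
#' @export
carries <- function(a, b, p) {
  stopifnot(length(a) == 1L, length(b) == 1L, length(p) == 1L)
  if (a < 1 || b < 1 || a != round(a) || b != round(b)) {
    stop("a and b must be positive integers")
  }
  if (p != round(p) || !is_prime(p)) stop("p must be prime")
  total <- 0L
  carry <- 0L
  s <- a + b
  while (s > 0) {
    carry <- if (a %% p + b %% p + carry < p) 0L else 1L
    total <- total + carry
    a <- a %/% p
    b <- b %/% p
    s <- s %/% p
  }
  total
}

#' Parity of the central binomial coefficient for odd n
#'
#' For `n = 2m + 1`, `choose(n, m)` is odd exactly when `n + 1` is a power of
#' two (a direct consequence of Kummer's theorem in base 2). This parity
#' decides whether the compatibility graph of the maximum-size splits admits a
#' perfect matching or only a defect-1 matching.
#'
#' @param n An odd integer `>= 3`.
#' @return Logical: is `choose(n, (n-1)/2)` odd?
#' @examples
#' central_binomial_is_odd(7)   # TRUE: choose(7,3) = 35
#' central_binomial_is_odd(5)   # FALSE: choose(5,2) = 10
#' @export
central_binomial_is_odd <- function(n) {
  if (length(n) != 1L || is.na(n) || n != round(n) || n %% 2 == 0 || n < 3) {
    stop("n must be an odd integer >= 3 (n = 2m + 1 with m >= 1)")
  }
  n <- as.integer(n)
  bitwAnd(n + 1L, n) == 0L
}

#' Symmetric chain decomposition of the small half of the subset lattice
#'
#' Partitions the non-empty subsets of the taxa set of size at most
#' `m = floor(n/2)` into `choose(n, m)` inclusion chains with consecutive
#' sizes, each containing exactly one subset of size `m`. Uses the
#' bracket-matching construction (element present = an opening bracket,
#' absent = closing; a chain fixes the matched positions and grows through the
#' unmatched ones), so the result is deterministic for a fixed taxa order.
#'
#' @param taxa A taxa set.
#' @return An object of class `"chain_decomposition"` with fields `labels`,
#'   `m`, and `chains` (a list of lists of index vectors, each chain ordered
#'   by increasing size).
#' @examples
#' cd <- symmetric_chain_decomposition(taxa_set(5))
#' length(cd$chains)  # choose(5, 2) = 10
#' @export
symmetric_chain_decomposition <- function(taxa) {
  labels <- taxa_set(taxa)
  n <- length(labels)
  m <- n %/% 2L
  subsets <- unlist(lapply(seq_len(m), function(k) {
    utils::combn(seq_len(n), k, simplify = FALSE)
  }), recursive = FALSE)
  keys <- vapply(subsets, function(s) side_key(bracket_anchor(s, n)), "")
  groups <- split(subsets, keys)
  chains <- lapply(groups, function(g) g[order(lengths(g))])
  # order chains by their (unique) size-m member, lexicographically
  tops <- vapply(chains, function(ch) {
    top <- ch[[length(ch)]]
    paste(sprintf("%05d", top), collapse = ",")
  }, "")
  chains <- chains[order(tops)]
  names(chains) <- NULL
  cd <- structure(list(labels = labels, m = m, chains = chains),
                  class = "chain_decomposition")
  validate_chain_decomposition(cd)
  cd
}

# Matched element positions of a subset under bracket matching: scan left to
# right, members push, non-members pop. The matched positions are invariant
# along a symmetric chain, so they identify the chain.
bracket_anchor <- function(s, n) {
  mem <- logical(n)
  mem[s] <- TRUE
  stack <- integer(0)
  matched <- logical(n)
  for (i in seq_len(n)) {
    if (mem[i]) {
      stack <- c(stack, i)
    } else if (length(stack)) {
      matched[stack[length(stack)]] <- TRUE
      stack <- stack[-length(stack)]
    }
  }
  which(matched)
}

validate_chain_decomposition <- function(cd) {
  n <- length(cd$labels)
  m <- cd$m
  if (length(cd$chains) != choose(n, m)) {
    stop("internal error: expected ", choose(n, m), " chains")
  }
  total <- 0L
  for (ch in cd$chains) {
    sizes <- lengths(ch)
    if (sum(sizes == m) != 1L) stop("internal error: chain without a unique size-m subset")
    if (length(ch) > 1L) {
      if (any(diff(sizes) != 1L)) stop("internal error: chain sizes not consecutive")
      for (i in seq_len(length(ch) - 1L)) {
        if (!all(ch[[i]] %in% ch[[i + 1L]])) stop("internal error: chain not nested")
      }
    }
    total <- total + length(ch)
  }
  if (total != sum(choose(n, seq_len(m)))) {
    stop("internal error: chains do not cover all subsets of size <= m")
  }
  invisible(cd)
}

#' @export
print.chain_decomposition <- function(x, ...) {
  cat(sprintf("Symmetric chain decomposition: %d chains on %d taxa (m = %d)\n",
              length(x$chains), length(x$labels), x$m))
  invisible(x)
}

#' Map a subset to its split
#'
#' The map `A -> A | (X \ A)` from non-empty proper subsets onto splits. It is
#' injective for odd n; for even n it identifies complementary subsets of
#' size n/2 (and only those).
#'
#' @param subset Labels or indices of the subset.
#' @param taxa A taxa set.
#' @return A `"split"` object.
#' @export
gamma_split <- function(subset, taxa) make_split(subset, taxa)

#' Compatibility graph of the size-m splits
#'
#' Vertices are all splits of size `m` on the taxa set (`Bip(n, m)`); two
#' distinct vertices are joined iff they are Buneman-compatible. For size-m
#' splits this is equivalent to their m-element parts being disjoint, which is
#' how edges are enumerated. For even `n = 2m` the graph has no edges (a tree
#' displays at most one split of size m); for odd `n = 2m + 1` it is a
#' connected, (m+1)-regular, vertex-transitive graph.
#'
#' @param taxa A taxa set.
#' @param m Split size, `1 <= m <= floor(n/2)`; defaults to `floor(n/2)`.
#' @return An object of class `"compat_graph"` with fields `labels`, `m`,
#'   `vertices` (list of m-element small sides, as index vectors) and `edges`
#'   (two-column matrix of vertex indices).
#' @examples
#' G <- bip_compatibility_graph(taxa_set(5))
#' length(G$vertices)  # 10
#' @export
bip_compatibility_graph <- function(taxa, m = NULL) {
  labels <- taxa_set(taxa)
  n <- length(labels)
  if (is.null(m)) m <- n %/% 2L
  m <- as.integer(m)
  if (m < 1L || m > n %/% 2L) stop("m must be between 1 and floor(n/2)")
  if (n == 2L * m) {
    # each split of size m corresponds to one m-subset avoiding taxon 1
    verts <- combn_list(seq.int(2L, n), m)
  } else {
    verts <- utils::combn(seq_len(n), m, simplify = FALSE)
  }
  key <- vapply(verts, side_key, "")
  lut <- stats::setNames(seq_along(verts), key)
  ii <- integer(0); jj <- integer(0)
  for (i in seq_along(verts)) {
    rest <- setdiff(seq_len(n), verts[[i]])
    if (length(rest) < m) next
    nb <- combn_list(rest, m)
    j <- unname(lut[vapply(nb, side_key, "")])
    j <- j[!is.na(j) & j > i]
    ii <- c(ii, rep.int(i, length(j))); jj <- c(jj, j)
  }
  structure(list(labels = labels, n = n, m = m, vertices = verts,
                 edges = cbind(ii, jj, deparse.level = 0)),
            class = "compat_graph")
}

#' @export
print.compat_graph <- function(x, ...) {
  cat(sprintf("Compatibility graph of Bip(%d, %d): %d vertices, %d edges\n",
              x$n, x$m, length(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Maximum matching on a compatibility graph
#'
#' Runs a general (blossom) maximum-matching algorithm on the graph. For the
#' compatibility graph of `Bip(2m+1, m)` with `m >= 2` the defect of a maximum
#' matching is known: 1 when `n = 2^k - 1` (odd vertex count), 0 otherwise;
#' a larger defect signals a construction bug and raises an error.
#'
#' @param G A `"compat_graph"`.
#' @return An object of class `"split_matching"`: `pairs` (two-column matrix
#'   of matched vertex indices), `unmatched` (vertex indices), `defect`.
#' @examples
#' M <- max_matching(bip_compatibility_graph(taxa_set(5)))
#' M$defect  # 0
#' @export
max_matching <- function(G) {
  stopifnot(inherits(G, "compat_graph"))
  nv <- length(G$vertices)
  mate <- blossom_max_matching(nv, G$edges)
  unmatched <- which(mate == 0L)
  pairs <- cbind(which(mate > seq_len(nv)), mate[mate > seq_len(nv)],
                 deparse.level = 0)
  defect <- length(unmatched)
  if (G$n == 2L * G$m + 1L && G$m >= 2L && G$m == G$n %/% 2L) {
    expected <- if (central_binomial_is_odd(G$n)) 1L else 0L
    if (defect != expected) {
      stop("internal error: maximum matching on Bip(", G$n, ",", G$m,
           ") has defect ", defect, ", expected ", expected)
    }
  }
  structure(list(pairs = pairs, unmatched = unmatched, defect = defect),
            class = "split_matching")
}

#' @export
print.split_matching <- function(x, ...) {
  cat(sprintf("Matching: %d pairs, defect %d\n", nrow(x$pairs), x$defect))
  invisible(x)
}

#' Overlap statistic of two maximum-size splits on an odd taxa set
#'
#' For two size-m splits on `n = 2m + 1` taxa, returns the size of the
#' intersection of their (m+1)-element parts. It equals `m + 1` iff the splits
#' coincide, and strictly increases along the walk used to show that the
#' compatibility graph of `Bip(n, m)` is connected.
#'
#' @param s1,s2 `"split"` objects of size m on the same odd-sized taxa set.
#' @return An integer in `1..(m+1)`.
#' @export
intersection_stat <- function(s1, s2) {
  stopifnot(inherits(s1, "split"), inherits(s2, "split"))
  if (!same_taxa(s1, s2)) stop("splits are on different taxa sets")
  n <- s1$n
  if (n %% 2L == 0L) stop("intersection_stat requires an odd number of taxa")
  m <- n %/% 2L
  if (split_size(s1) != m || split_size(s2) != m) {
    stop("both splits must have the maximum size m = ", m)
  }
  big <- function(s) {
    if (length(s$side) == m + 1L) s$side else setdiff(seq_len(n), s$side)
  }
  length(intersect(big(s1), big(s2)))
}

#' Construct a minimal universal tree set
#'
#' Builds `universal_size(n)` trees that together display every split on the
#' taxa set. The construction follows the constructive argument behind the
#' closed form: take a symmetric chain decomposition of the subsets of size at
#' most m; map each chain to a nested (hence compatible) family of splits; for
#' even n merge the two chains carrying complementary size-m subsets, for odd
#' n merge chains paired by a maximum matching on the compatibility graph of
#' the size-m splits (one chain is left alone when `choose(n, m)` is odd);
#' each merged class is pairwise compatible and becomes one tree.
#'
#' @param taxa A taxa set (or an integer number of taxa).
#' @return A `"tree_set"` of exactly `universal_size(n)` trees, with the
#'   per-tree split classes attached as attribute `"classes"` (a list of
#'   `"split_system"` objects).
#' @examples
#' ts <- build_universal_tree_set(5)
#' length(ts)                       # 5
#' displays(ts, all_splits(5))      # TRUE
#' @export
build_universal_tree_set <- function(taxa) {
  labels <- taxa_set(taxa)
  n <- length(labels)
  if (n <= 3L) {
    star <- tree_from_splits(split_system(list(), labels))
    ts <- tree_set(list(star), labels)
    attr(ts, "classes") <- list(split_system(list(), labels))
    return(ts)
  }
  m <- n %/% 2L
  cd <- symmetric_chain_decomposition(labels)
  k <- length(cd$chains)
  tops <- lapply(cd$chains, function(ch) ch[[which(lengths(ch) == m)]])
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) { parent[find(i)] <<- find(j) }

  top_key <- vapply(tops, side_key, "")
  lut <- stats::setNames(seq_len(k), top_key)
  if (n %% 2L == 0L) {
    # merge the chain of A with the chain of X \ A (same split of size m)
    for (i in seq_len(k)) {
      comp <- setdiff(seq_len(n), tops[[i]])
      j <- unname(lut[side_key(comp)])
      if (is.na(j)) stop("internal error: complement chain not found")
      if (find(i) != find(j)) union2(i, j)
    }
  } else {
    G <- bip_compatibility_graph(labels, m)
    M <- max_matching(G)
    vkey <- vapply(G$vertices, side_key, "")
    if (nrow(M$pairs)) {
      for (r in seq_len(nrow(M$pairs))) {
        i <- unname(lut[vkey[M$pairs[r, 1L]]])
        j <- unname(lut[vkey[M$pairs[r, 2L]]])
        union2(i, j)
      }
    }
  }
  roots <- vapply(seq_len(k), find, 0L)
  comp_ids <- split(seq_len(k), roots)
  expected <- universal_size(n)
  if (length(comp_ids) != expected) {
    stop("internal error: ", length(comp_ids), " components, expected ", expected)
  }
  classes <- lapply(comp_ids, function(ids) {
    sides <- lapply(unlist(cd$chains[ids], recursive = FALSE),
                    canonical_side, n = n)
    cls <- new_split_system(sides, labels)
    if (!is_pairwise_compatible(cls)) {
      stop("internal error: constructed class is not pairwise compatible")
    }
    cls
  })
  # deterministic order: by the canonical string of each class's first split
  ord <- order(vapply(classes, function(cl) side_key(cl$sides[[1L]]), ""))
  classes <- classes[ord]
  names(classes) <- NULL
  trees <- lapply(classes, tree_from_splits)
  ts <- tree_set(trees, labels)
  attr(ts, "classes") <- classes
  ts
}
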