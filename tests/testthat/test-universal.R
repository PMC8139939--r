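test_that("universal incompatibility closed form", {
  expect_equal(universal_size(2), 1)
  expect_equal(universal_size(3), 1)  # star tree displays all (trivial) splits
  expect_equal(universal_size(5), 5)
  expect_equal(sapply(4:9, universal_size), c(3, 5, 10, 18, 35, 63))
  expect_equal(universal_size(12), 462)
  expect_equal(universal_size(13), 858)
  expect_error(universal_size(1), "at least 2")
  expect_error(universal_size(4.5), "integer")
  # non-decreasing from n = 3 on
  u <- sapply(3:16, universal_size)
  expect_true(all(diff(u) >= 0))
})

test_that("carries implements the base-p digit recurrence", {
  expect_equal(carries(15, 4, 2), 2L)
  expect_equal(carries(1, 1, 2), 1L)
  expect_error(carries(3, 4, 6), "prime")
  expect_error(carries(0, 1, 2), "positive")
})

test_that("carries equals the p-adic valuation of choose(a+b, a) (Kummer)", {
  for (p in c(2, 3, 5)) {
    for (a in seq_len(32)) {
      for (b in seq_len(32)) {
        expect_identical(carries(a, b, p),
                         as.integer(oracle_padic_valuation_binom(a, b, p)),
                         label = sprintf("carries(%d,%d,%d)", a, b, p))
      }
    }
  }
})

test_that("central binomial parity: odd iff n+1 is a power of two", {
  expect_true(central_binomial_is_odd(7))    # choose(7,3) = 35
  expect_true(central_binomial_is_odd(15))   # choose(15,7) = 6435
  expect_false(central_binomial_is_odd(5))   # choose(5,2) = 10
  expect_error(central_binomial_is_odd(6), "odd")
  for (n in seq(3, 25, by = 2)) {
    expect_identical(central_binomial_is_odd(n),
                     choose(n, (n - 1) / 2) %% 2 == 1)
  }
})

test_that("symmetric chain decomposition satisfies all lattice invariants", {
  cd4 <- symmetric_chain_decomposition(taxa_set(4))
  expect_length(cd4$chains, 6L)
  expect_true(all(vapply(cd4$chains, function(ch) sum(lengths(ch) == 2) == 1, NA)))

  cd5 <- symmetric_chain_decomposition(taxa_set(5))
  expect_length(cd5$chains, 10L)
  chain_lens <- table(lengths(cd5$chains))
  expect_equal(as.integer(chain_lens[c("1", "2")]), c(5L, 5L))
  singleton_starts <- sum(vapply(cd5$chains, function(ch) {
    length(ch[[1L]]) == 1L
  }, NA))
  expect_equal(singleton_starts, 5L)

  # exhaustive coverage: every non-empty subset of size <= m in exactly one chain
  for (n in 4:8) {
    cd <- symmetric_chain_decomposition(taxa_set(n))
    m <- n %/% 2L
    seen <- unlist(lapply(cd$chains, function(ch) {
      vapply(ch, function(s) paste(s, collapse = ","), "")
    }))
    expect_false(anyDuplicated(seen) > 0)
    want <- unlist(lapply(seq_len(m), function(k) {
      vapply(utils::combn(n, k, simplify = FALSE),
             function(s) paste(s, collapse = ","), "")
    }))
    expect_setequal(seen, want)
  }
})

test_that("gamma maps subsets to splits, non-injective only for even n", {
  X5 <- taxa_set(5)
  expect_identical(gamma_split(c(1, 2), X5), make_split(c(1, 2), X5))
  X4 <- taxa_set(4)
  expect_identical(gamma_split(c(1, 2), X4), gamma_split(c(3, 4), X4))
  # odd n: injective on subsets of size <= m
  keys <- character(0)
  for (k in 1:2) {
    for (s in utils::combn(5, k, simplify = FALSE)) {
      g <- gamma_split(s, X5)
      keys <- c(keys, paste(g$side, collapse = ","))
    }
  }
  expect_false(anyDuplicated(keys) > 0)
})

test_that("compatibility graph of Bip(n,m): counts, regularity, connectivity", {
  G <- bip_compatibility_graph(taxa_set(5))
  expect_length(G$vertices, 10L)
  deg <- tabulate(as.vector(G$edges), nbins = 10L)
  expect_true(all(deg == 3L))  # (m+1)-regular for n = 2m+1
  g <- igraph::graph_from_edgelist(G$edges, directed = FALSE)
  expect_true(igraph::is_connected(g))

  # even n: isolated vertices only (a tree holds at most one size-m split)
  for (n in c(4, 6)) {
    Ge <- bip_compatibility_graph(taxa_set(n))
    expect_length(Ge$vertices, choose(n, n / 2) / 2)
    expect_equal(nrow(Ge$edges), 0L)
  }

  # edges agree with the pairwise Buneman relation, exhaustively, n = 5..7
  for (n in 5:7) {
    Gx <- bip_compatibility_graph(taxa_set(n))
    sp <- lapply(Gx$vertices, make_split, taxa = taxa_set(n))
    in_graph <- matrix(FALSE, length(sp), length(sp))
    in_graph[Gx$edges] <- TRUE
    for (i in seq_along(sp)) {
      for (j in seq_along(sp)[-seq_len(i)]) {
        expect_identical(in_graph[i, j] || in_graph[j, i],
                         are_compatible(sp[[i]], sp[[j]]))
      }
    }
  }
})

test_that("maximum matching defect follows the central binomial parity", {
  for (n in c(5, 9, 11)) {
    M <- max_matching(bip_compatibility_graph(taxa_set(n)))
    expect_equal(M$defect, 0L)
  }
  M7 <- max_matching(bip_compatibility_graph(taxa_set(7)))
  expect_equal(M7$defect, 1L)
  # matching validity: matched pairs are edges and vertex-disjoint
  G <- bip_compatibility_graph(taxa_set(7))
  M <- max_matching(G)
  expect_false(anyDuplicated(as.vector(M$pairs)) > 0)
  ek <- paste(G$edges[, 1], G$edges[, 2])
  mk <- paste(pmin(M$pairs[, 1], M$pairs[, 2]), pmax(M$pairs[, 1], M$pairs[, 2]))
  expect_true(all(mk %in% ek))
  expect_equal(2L * nrow(M$pairs) + M$defect, length(G$vertices))
})

test_that("overlap statistic of maximum-size splits drives the connectivity walk", {
  X <- taxa_set(5)
  s <- make_split(c(1, 2), X)
  expect_equal(intersection_stat(s, s), 3L)  # m + 1
  expect_equal(intersection_stat(make_split(c(1, 2), X), make_split(c(3, 4), X)),
               1L)  # |{3,4,5} ∩ {1,2,5}|
  expect_error(intersection_stat(make_split(1, X), s), "maximum size")

  # replay of the connectivity argument on n = 5: from any vertex one can walk
  # to any target so that the overlap with the target never decreases and
  # strictly increases every two steps
  G <- bip_compatibility_graph(X)
  sp <- lapply(G$vertices, make_split, taxa = X)
  adj <- vector("list", length(sp))
  for (r in seq_len(nrow(G$edges))) {
    i <- G$edges[r, 1]; j <- G$edges[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  m <- 2L
  for (from in seq_along(sp)) {
    for (target in seq_along(sp)) {
      cur <- from
      hops <- 0L
      while (cur != target && hops <= 2L * (m + 1L)) {
        k0 <- intersection_stat(sp[[cur]], sp[[target]])
        # within two edges there is always a vertex with strictly larger
        # overlap with the target (the overlap is m+1 only at the target)
        reach <- unique(c(adj[[cur]], unlist(adj[adj[[cur]]])))
        better <- reach[vapply(reach, function(v) {
          intersection_stat(sp[[v]], sp[[target]]) > k0
        }, NA)]
        expect_gt(length(better), 0)
        cur <- better[1L]
        hops <- hops + 1L
      }
      expect_identical(cur, target)
    }
  }
})

test_that("constructed universal tree sets are minimal and universal, n = 2..9", {
  for (n in 2:9) {
    ts <- build_universal_tree_set(n)
    expect_length(ts, universal_size(n))
    expect_true(displays(ts, all_splits(n)))
    if (n >= 4) {
      m <- n %/% 2L
      cap <- if (n %% 2L == 0L) 1L else 2L
      for (tr in unclass(ts)) {
        sz <- vapply(system_splits(splits_of_tree(tr, taxa_set(n))),
                     split_size, 0L)
        expect_lte(sum(sz == m), cap)
      }
    }
  }
})

test_that("even-n universal trees carry nested-or-disjoint nontrivial splits", {
  for (n in c(6, 8)) {
    ts <- build_universal_tree_set(n)
    for (cl in attr(ts, "classes")) {
      sides <- lapply(system_splits(cl, nontrivial = TRUE), function(s) s$side)
      if (length(sides) < 2) next
      for (i in seq_len(length(sides) - 1L)) {
        for (j in seq.int(i + 1L, length(sides))) {
          a <- sides[[i]]; b <- sides[[j]]
          nested_or_disjoint <- all(a %in% b) || all(b %in% a) ||
            length(intersect(a, b)) == 0L
          expect_true(nested_or_disjoint)
        }
      }
    }
  }
})
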