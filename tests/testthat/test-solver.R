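test_that("incompatibility graph of the five-cycle example is a 5-cycle", {
  ig <- incompatibility_graph(example_cycle_system())
  expect_length(ig$sides, 5L)
  expect_equal(nrow(ig$edges), 5L)
  deg <- tabulate(as.vector(ig$edges), nbins = 5L)
  expect_true(all(deg == 2L))
  g <- igraph::graph_from_edgelist(ig$edges, directed = FALSE)
  expect_true(igraph::is_connected(g))

  # pairwise-compatible system -> edgeless graph
  ig2 <- incompatibility_graph(random_compatible_system(7, 1))
  expect_equal(nrow(ig2$edges), 0L)

  # all nontrivial splits on 5 taxa: 10 vertices, regular
  ig3 <- incompatibility_graph(all_splits(5, nontrivial = TRUE))
  expect_length(ig3$sides, 10L)
  deg3 <- tabulate(as.vector(ig3$edges), nbins = 10L)
  expect_true(all(deg3 == deg3[1L]))
})

test_that("largest pairwise-incompatible subset (k-compatibility)", {
  expect_equal(max_incompatible_subset_size(example_cycle_system()), 2L)
  expect_equal(max_incompatible_subset_size(random_compatible_system(6, 2)), 1L)
  expect_equal(max_incompatible_subset_size(split_system(list(), taxa_set(4))), 0L)
  # agreement with subset-enumeration brute force on random systems
  for (seed in 1:25) {
    S <- generate_split_system(6, 2, 4, seed = seed)
    expect_identical(max_incompatible_subset_size(S),
                     as.integer(oracle_max_incompatible(S)),
                     label = paste("seed", seed))
  }
})

test_that("capacity lower bound from per-tree display limits", {
  expect_equal(capacity_lower_bound(example_cycle_system()), 3L)
  expect_equal(capacity_lower_bound(split_system(list(), taxa_set(6))), 0L)
  # full split set on 12 taxa: choose(12,6)/2 size-6 splits, one per tree
  expect_equal(capacity_lower_bound(all_splits(12)), 462L)
  # n - 3 capacity dominates when there are many small splits
  S <- all_splits(6, nontrivial = TRUE)
  expect_gte(capacity_lower_bound(S), ceiling(25 / 3))
})

test_that("exact minimal tree set size on the worked five-split example", {
  sol <- min_tree_set(example_cycle_system())
  expect_equal(sol$k, 3L)
  expect_true(sol$optimal)
  expect_equal(sol$clique_bound, 2L)      # 2-compatible ...
  expect_equal(sol$capacity_bound, 3L)    # ... yet three trees are needed
  expect_equal(sol$lower_bound, 3L)
  expect_true(displays(sol$trees, example_cycle_system()))
  expect_true(all(vapply(sol$classes, is_pairwise_compatible, NA)))
  # classes partition the nontrivial splits exactly
  got <- sort(unlist(lapply(sol$classes, function(cl) {
    vapply(cl$sides, function(s) paste(s, collapse = ","), "")
  })))
  want <- sort(vapply(example_cycle_system()$sides,
                      function(s) paste(s, collapse = ","), ""))
  expect_identical(got, want)
})

test_that("kappa of full split sets equals the universal incompatibility", {
  for (n in 5:7) {
    sol <- min_tree_set(all_splits(n, nontrivial = TRUE))
    expect_true(sol$optimal)
    expect_equal(sol$k, as.integer(universal_size(n)))
  }
})

test_that("kappa degenerate cases: trees, all-trivial, empty", {
  S <- random_compatible_system(8, 11)
  expect_equal(min_tree_set(S)$k, 1L)
  triv <- split_system(as.list(1:5), taxa_set(5))
  sol <- min_tree_set(triv)
  expect_equal(sol$k, 1L)
  expect_true(displays(sol$trees, triv))
  empty <- split_system(list(), taxa_set(5))
  sol0 <- min_tree_set(empty)
  expect_equal(sol0$k, 0L)
  expect_true(sol0$optimal)
})

test_that("exact solver equals brute-force partition minimum on seeded systems", {
  for (seed in 1:60) {
    n <- 5L + (seed %% 3L)
    S <- generate_split_system(n, 2, 3, seed = seed)
    if (length(system_splits(S, nontrivial = TRUE)) > 8L) next
    sol <- min_tree_set(S)
    expect_true(sol$optimal)
    expect_identical(sol$k, as.integer(oracle_min_partition(S)),
                     label = paste("seed", seed))
    expect_true(displays(sol$trees, S))
  }
})

test_that("solution bounds sandwich k and degrade honestly under a budget", {
  for (seed in 1:20) {
    S <- generate_split_system(7, 3, 4, seed = seed)
    sol <- min_tree_set(S)
    expect_lte(sol$clique_bound, sol$k)
    expect_lte(sol$capacity_bound, sol$k)
    expect_lte(sol$lower_bound, sol$k)
    expect_gte(sol$upper_bound, sol$lower_bound)
  }
  # zero budget: greedy classes with optimal only if bounds already met
  S <- all_splits(6, nontrivial = TRUE)
  sol <- min_tree_set(S, budget = 0)
  expect_gte(sol$upper_bound, sol$lower_bound)
  expect_true(displays(sol$trees, S))
  if (!sol$optimal) expect_gt(sol$upper_bound, sol$lower_bound)
})

test_that("adding a split never decreases kappa", {
  for (seed in 1:10) {
    S <- generate_split_system(6, 2, 2, seed = seed)
    k0 <- min_tree_set(S)$k
    extra <- generate_split_system(6, 1, 5, seed = seed + 1000L)
    grown <- split_system(c(S$sides, extra$sides), taxa_set(6))
    expect_gte(min_tree_set(grown)$k, k0)
  }
})

test_that("normalized tree set size is an exact, comparable fraction", {
  r1 <- norm_ratio(4, 13)   # 4/858 reduced
  r2 <- norm_ratio(3, 12)   # 3/462 reduced
  expect_true(r1 < r2)
  expect_false(r1 > r2)
  expect_equal(r1$num / r1$den, 4 / 858)
  expect_equal(r2$num / r2$den, 3 / 462)
  expect_equal(as.numeric(norm_ratio(5, 5)), 1)

  # Norm(S(X)) = 1 by definition of U(n)
  r <- normalized_tree_set_size(all_splits(5, nontrivial = TRUE))
  expect_equal(r$num, 1)
  expect_equal(r$den, 1)

  # non-certified kappa is refused unless partial is allowed
  S <- all_splits(6, nontrivial = TRUE)
  sol <- min_tree_set(S, budget = 0)
  if (!sol$optimal) {
    expect_error(normalized_tree_set_size(S, budget = 0), "not certified")
  }
})

test_that("solutions serialize to the documented JSON shape", {
  sol <- min_tree_set(example_cycle_system())
  js <- jsonlite::fromJSON(solution_json(sol), simplifyVector = FALSE)
  expect_equal(js$k, 3L)
  expect_equal(js$u_of_n, 5L)
  expect_equal(js$norm, "3/5")
  expect_length(js$classes, 3L)
  expect_length(js$trees, 3L)
  expect_true(js$optimal)
})
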