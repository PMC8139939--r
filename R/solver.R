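#' Incompatibility graph of a split system
#'
#' One vertex per nontrivial split, one edge per incompatible pair. A
#' pairwise-compatible class of splits is an independent set of this graph, so
#' the minimal tree set size of the system is its chromatic number, and the
#' largest pairwise-incompatible subset is its maximum clique.
#'
#' @param S A `"split_system"`.
#' @return An object of class `"incompat_graph"`: `labels`, `sides` (canonical
#'   sides of the nontrivial splits, in canonical order), `adj` (logical
#'   adjacency matrix), `edges` (two-column matrix of vertex indices).
#' @export
incompatibility_graph <- function(S) {
  S <- split_system(S)
  n <- length(S$labels)
  sides <- nontrivial_sides(S)
  v <- length(sides)
  adj <- matrix(FALSE, v, v)
  if (v >= 2L) {
    for (i in seq_len(v - 1L)) {
      for (j in seq.int(i + 1L, v)) {
        if (!sides_compatible(sides[[i]], sides[[j]], n)) {
          adj[i, j] <- adj[j, i] <- TRUE
        }
      }
    }
  }
  edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  dimnames(edges) <- NULL
  structure(list(labels = S$labels, sides = sides, adj = adj, edges = edges),
            class = "incompat_graph")
}

#' @export
print.incompat_graph <- function(x, ...) {
  cat(sprintf("Incompatibility graph: %d nontrivial splits, %d incompatible pair(s)\n",
              length(x$sides), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(ig) {
  igraph::graph_from_edgelist(ig$edges, directed = FALSE) +
    igraph::vertices(setdiff(seq_along(ig$sides),
                             unique(as.vector(ig$edges))))
}

#' Largest pairwise-incompatible subset (k-compatibility level)
#'
#' The maximum number of splits in `S` that are mutually incompatible — the
#' clique number of the incompatibility graph, computed exactly. A system with
#' this value `k` is k-compatible. Returns 0 for an empty or all-trivial
#' system and 1 for a non-empty pairwise-compatible nontrivial system.
#'
#' @param S A `"split_system"`.
#' @return An integer.
#' @export
max_incompatible_subset_size <- function(S) {
  ig <- incompatibility_graph(S)
  v <- length(ig$sides)
  if (v == 0L) return(0L)
  if (nrow(ig$edges) == 0L) return(1L)
  as.integer(igraph::clique_num(as_igraph(ig)))
}

#' Capacity lower bound on the minimal tree set size
#'
#' Combines two per-tree display capacities: a tree on n taxa displays at most
#' one split of maximum size `m = floor(n/2)` when n is even and at most two
#' when n is odd, and at most `n - 3` nontrivial splits in total. With `c`
#' size-m splits and `t` nontrivial splits in `S`, the bound is
#' `max(c or ceiling(c/2), ceiling(t / (n - 3)))`.
#'
#' @param S A `"split_system"`.
#' @return An integer lower bound on `min_tree_set(S)$k`.
#' @export
capacity_lower_bound <- function(S) {
  S <- split_system(S)
  n <- length(S$labels)
  nt <- nontrivial_sides(S)
  if (n == 3L) return(as.integer(length(S$sides) > 0L))
  if (length(nt) == 0L) return(0L)
  m <- n %/% 2L
  cc <- sum(vapply(nt, function(s) min(length(s), n - length(s)), 0L) == m)
  b_m <- if (n %% 2L == 0L) cc else ceiling(cc / 2)
  b_gen <- ceiling(length(nt) / (n - 3L))
  as.integer(max(b_m, b_gen, 1L))
}

# Greedy colouring, largest incompatibility degree first. Returns an integer
# class vector.
greedy_classes <- function(adj) {
  v <- nrow(adj)
  deg <- rowSums(adj)
  ord <- order(-deg, seq_len(v))
  colr <- integer(v)
  for (u in ord) {
    taken <- unique(colr[adj[u, ] & colr > 0L])
    c0 <- 1L
    while (c0 %in% taken) c0 <- c0 + 1L
    colr[u] <- c0
  }
  colr
}

# Exact k-colourability by DSATUR-ordered branch and bound with symmetry
# breaking (a vertex may open at most one new colour). Returns an integer
# colouring, NULL if proven infeasible, or NA if the node budget ran out.
try_k_coloring <- function(adj, k, budget) {
  v <- nrow(adj)
  colr <- integer(v)
  deg <- rowSums(adj)
  nodes <- 0L
  rec <- function(n_colored, max_used) {
    if (n_colored == v) return(colr)
    nodes <<- nodes + 1L
    if (nodes > budget) return(NA)
    unc <- which(colr == 0L)
    sat <- vapply(unc, function(u) {
      length(unique(colr[adj[u, ] & colr > 0L]))
    }, 0L)
    u <- unc[order(-sat, -deg[unc], unc)][1L]
    taken <- unique(colr[adj[u, ] & colr > 0L])
    limit <- min(k, max_used + 1L)
    saw_budget <- FALSE
    for (c0 in seq_len(limit)) {
      if (c0 %in% taken) next
      colr[u] <<- c0
      res <- rec(n_colored + 1L, max(max_used, c0))
      colr[u] <<- 0L
      if (is.null(res)) next
      if (length(res) == 1L && is.na(res)) { saw_budget <- TRUE; next }
      return(res)
    }
    if (saw_budget) NA else NULL
  }
  rec(0L, 0L)
}

#' Exact minimal tree set size of a split system
#'
#' Computes `kappa(S)`: the least number of trees whose displayed splits cover
#' every split of `S`. Trivial splits are displayed by every tree, so this
#' equals the minimum number of pairwise-compatible classes partitioning the
#' nontrivial splits — the chromatic number of the incompatibility graph. The
#' solver takes a greedy upper bound, a lower bound from the exact clique
#' number and the per-tree capacities, and closes the gap by iterative
#' deepening with a DSATUR-ordered exact search. Each class plus the trivial
#' splits is materialised as one tree.
#'
#' @param S A `"split_system"`.
#' @param budget Node limit for the exact search. `NULL` (default) means
#'   unlimited for systems with at most 25 nontrivial splits and `2e5` nodes
#'   beyond that; if the budget is exhausted the best classes found are
#'   returned with `optimal = FALSE` and honest bounds.
#' @return An object of class `"tree_set_solution"` with fields `k`, `classes`
#'   (list of `"split_system"`), `trees` (a `"tree_set"`, `NULL` when `S` is
#'   empty), `lower_bound`, `upper_bound`, `optimal`, `clique_bound`,
#'   `capacity_bound`, `labels`.
#' @examples
#' X <- taxa_set(5)
#' S <- split_system(list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5)), X)
#' min_tree_set(S)$k  # 3
#' @export
min_tree_set <- function(S, budget = NULL) {
  S <- split_system(S)
  labels <- S$labels
  ig <- incompatibility_graph(S)
  v <- length(ig$sides)
  if (is.null(budget)) budget <- if (v <= 25L) Inf else 2e5
  clique_bound <- max_incompatible_subset_size(S)
  capacity_bound <- capacity_lower_bound(S)

  if (v == 0L) {
    k <- as.integer(length(S$sides) > 0L)  # one star tree, or nothing at all
    trees <- if (k == 1L) {
      tree_set(list(tree_from_splits(split_system(list(), labels))), labels)
    }
    return(new_solution(labels, S, k, classes = list(), trees = trees,
                        lb = k, ub = k, optimal = TRUE,
                        clique_bound, capacity_bound))
  }

  greedy <- greedy_classes(ig$adj)
  ub <- max(greedy)
  best <- greedy
  lb <- max(clique_bound, capacity_bound, 1L)
  proven_lb <- lb
  optimal <- FALSE
  if (ub <= lb) {
    optimal <- TRUE
  } else {
    for (k_try in seq.int(lb, ub - 1L)) {
      res <- try_k_coloring(ig$adj, k_try, budget)
      if (length(res) == 1L && is.na(res)) break  # budget: k_try undecided
      if (!is.null(res)) {
        best <- res
        ub <- k_try
        optimal <- TRUE
        break
      }
      proven_lb <- k_try + 1L  # k_try colours proven impossible
      if (proven_lb == ub) { optimal <- TRUE; break }
    }
  }
  k <- as.integer(ub)
  classes <- lapply(seq_len(max(best)), function(c0) {
    new_split_system(ig$sides[best == c0], labels)
  })
  trees <- tree_set(lapply(classes, tree_from_splits), labels)
  new_solution(labels, S, k, classes, trees,
               lb = as.integer(proven_lb), ub = k, optimal = optimal,
               clique_bound, capacity_bound)
}

new_solution <- function(labels, S, k, classes, trees, lb, ub, optimal,
                         clique_bound, capacity_bound) {
  structure(list(labels = labels, n = length(labels),
                 n_splits = length(S$sides),
                 n_nontrivial = length(nontrivial_sides(S)),
                 k = as.integer(k), classes = classes, trees = trees,
                 lower_bound = as.integer(lb), upper_bound = as.integer(ub),
                 optimal = optimal, clique_bound = as.integer(clique_bound),
                 capacity_bound = as.integer(capacity_bound)),
            class = "tree_set_solution")
}

#' @export
print.tree_set_solution <- function(x, ...) {
  cat(sprintf("Minimal tree set: k = %d (%s) on %d taxa\n", x$k,
              if (x$optimal) "optimal" else
                sprintf("bounds %d..%d", x$lower_bound, x$upper_bound),
              x$n))
  cat(sprintf("  %d split(s), %d nontrivial; clique bound %d, capacity bound %d\n",
              x$n_splits, x$n_nontrivial, x$clique_bound, x$capacity_bound))
  invisible(x)
}

#' Serialize a solution to JSON
#'
#' @param sol A `"tree_set_solution"`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return A JSON string (invisibly, when written to a file).
#' @export
solution_json <- function(sol, path = NULL) {
  stopifnot(inherits(sol, "tree_set_solution"))
  u <- universal_size(sol$n)
  norm <- if (sol$optimal) {
    r <- norm_ratio(sol$k, sol$n)
    paste0(r$num, "/", r$den)
  } else NA
  obj <- list(
    n = sol$n, n_splits = sol$n_splits, n_nontrivial = sol$n_nontrivial,
    k = sol$k, lower_bound = sol$lower_bound, upper_bound = sol$upper_bound,
    optimal = sol$optimal, clique_bound = sol$clique_bound,
    capacity_bound = sol$capacity_bound, u_of_n = u, norm = norm,
    classes = lapply(sol$classes, function(cl) {
      I(vapply(cl$sides, format_side, "", labels = sol$labels))
    }),
    trees = I(if (is.null(sol$trees)) character(0) else
      vapply(unclass(sol$trees), function(tr) ape::write.tree(tr), ""))
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Normalized tree set size
#'
#' `Norm(S) = kappa(S) / U(n)` as an exact reduced fraction, comparable across
#' different taxa counts. Refuses a non-optimal kappa unless `partial = TRUE`.
#'
#' @param S A `"split_system"`.
#' @param budget Passed to [min_tree_set()].
#' @param partial Accept a non-certified kappa (uses the upper bound)?
#' @return A `"norm_fraction"`: exact numerator/denominator plus its numeric
#'   value; comparison operators work exactly (by cross-multiplication).
#' @export
normalized_tree_set_size <- function(S, budget = NULL, partial = FALSE) {
  S <- split_system(S)
  sol <- min_tree_set(S, budget = budget)
  if (!sol$optimal && !partial) {
    stop("kappa not certified optimal (bounds ", sol$lower_bound, "..",
         sol$upper_bound, "); rerun with a larger budget or partial = TRUE")
  }
  norm_ratio(sol$k, sol$n)
}

#' Exact ratio kappa / U(n)
#'
#' @param kappa A minimal tree set size (e.g. computed by [min_tree_set()],
#'   or taken from a published analysis).
#' @param n The number of taxa.
#' @return A `"norm_fraction"` object.
#' @examples
#' norm_ratio(4, 13) < norm_ratio(3, 12)  # TRUE: 4/858 < 3/462
#' @export
norm_ratio <- function(kappa, n) {
  stopifnot(kappa == round(kappa), kappa >= 0)
  u <- universal_size(n)
  g <- gcd2(kappa, u)
  structure(list(num = kappa / g, den = u / g, value = kappa / u),
            class = "norm_fraction")
}

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  max(a, 1)
}

#' @export
print.norm_fraction <- function(x, ...) {
  cat(sprintf("%d/%d (= %.6g)\n", x$num, x$den, x$value))
  invisible(x)
}

#' @export
Ops.norm_fraction <- function(e1, e2) {
  if (!.Generic %in% c("<", ">", "<=", ">=", "==", "!=")) {
    stop("operation '", .Generic, "' not defined for norm_fraction")
  }
  if (!inherits(e1, "norm_fraction") || !inherits(e2, "norm_fraction")) {
    stop("both operands must be norm_fraction objects")
  }
  # exact comparison by cross-multiplication
  get(.Generic)(e1$num * e2$den, e2$num * e1$den)
}

#' @export
as.double.norm_fraction <- function(x, ...) x$value
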