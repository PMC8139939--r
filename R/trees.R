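#' Bundle trees on a common taxa set
#'
#' A tree set is a list of unrooted phylogenetic trees (`ape::phylo`) whose tip
#' labels all equal one taxa set. It doubles as an `ape` `multiPhylo` object.
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`).
#' @param taxa The shared taxa set; defaults to the first tree's tip labels.
#' @return An object of class `c("tree_set", "multiPhylo")`.
#' @export
tree_set <- function(trees, taxa = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0L) stop("a tree set must contain at least one tree")
  if (is.null(taxa)) taxa <- trees[[1L]]$tip.label
  labels <- taxa_set(taxa)
  for (tr in trees) {
    if (!inherits(tr, "phylo")) stop("tree set members must be 'phylo' objects")
    if (!setequal(tr$tip.label, labels) ||
        length(tr$tip.label) != length(labels)) {
      stop("all trees must be labelled by the same taxa set")
    }
  }
  structure(trees, class = c("tree_set", "multiPhylo"), taxa = labels)
}

#' @export
print.tree_set <- function(x, ...) {
  cat(sprintf("Tree set: %d tree(s) on %d taxa\n",
              length(x), length(attr(x, "taxa"))))
  invisible(x)
}

#' Split system induced by a tree
#'
#' Deleting any edge of an unrooted phylogenetic tree disconnects it into two
#' leaf sets, giving one split per edge. The result always contains the n
#' trivial splits (leaf edges) and is pairwise compatible.
#'
#' @param tree A `phylo` object (a degree-2 root, if present, is suppressed).
#' @param taxa Optional taxa set fixing the index order; defaults to the
#'   tree's tip labels in their stored order.
#' @return A `"split_system"` containing one split per edge.
#' @examples
#' tr <- ape::read.tree(text = "((1,2),(3,4),5);")
#' splits_of_tree(tr)
#' @export
splits_of_tree <- function(tree, taxa = NULL) {
  stopifnot(inherits(tree, "phylo"))
  labels <- if (is.null(taxa)) taxa_set(tree$tip.label) else taxa_set(taxa)
  n <- length(labels)
  idx <- match(tree$tip.label, labels)
  if (anyNA(idx) || length(tree$tip.label) != n) {
    stop("tree tips do not match the taxa set")
  }
  tree <- ape::collapse.singles(tree)
  if (n > 3L && ape::is.rooted(tree)) tree <- ape::unroot(tree)
  sides <- list()
  if (tree$Nnode > 1L) {
    pp <- ape::prop.part(tree)
    clades <- lapply(pp, function(cl) idx[cl])
    sides <- Filter(function(s) length(s) < n, clades)
  }
  sides <- c(sides, as.list(seq_len(n)))  # trivial splits from leaf edges
  sides <- lapply(sides, canonical_side, n = n)
  new_split_system(sides, labels)
}

#' Build the unique tree displaying a pairwise-compatible split system
#'
#' By the splits equivalence theorem a pairwise-compatible split system plus
#' all trivial splits is induced by exactly one tree (up to isomorphism). The
#' canonical sides (not containing taxon 1) of the nontrivial splits form a
#' laminar family; the tree is its nesting forest, rooted at the interior
#' vertex on taxon 1's side of every split, with no extra refinement.
#'
#' @param S A pairwise-compatible `"split_system"` (trivial splits may be
#'   present or absent; they are implied by the leaf edges).
#' @return A `phylo` object.
#' @examples
#' X <- taxa_set(5)
#' tr <- tree_from_splits(split_system(list(c(1, 2), c(3, 4)), X))
#' @export
tree_from_splits <- function(S) {
  S <- split_system(S)
  labels <- S$labels
  n <- length(labels)
  bad <- first_incompatible_pair(S)
  if (!is.null(bad)) {
    stop("split system is incompatible: ",
         format_side(S$sides[[bad[1L]]], labels), "  vs  ",
         format_side(S$sides[[bad[2L]]], labels))
  }
  sides <- nontrivial_sides(S)
  txt <- paste0(newick_node(seq_len(n), sides, labels), ";")
  tr <- ape::read.tree(text = txt)
  tr
}

quote_label <- function(x) {
  needs <- grepl("[][ ():,;']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

# Recursive Newick for the nesting forest of a laminar family of canonical
# sides contained in `elements`. Children are ordered by smallest taxon index
# so output is deterministic for a fixed input.
newick_node <- function(elements, sides, labels) {
  maximal <- Filter(function(s) {
    !any(vapply(sides, function(t) {
      length(t) > length(s) && all(s %in% t)
    }, NA))
  }, sides)
  covered <- unique(unlist(maximal))
  free <- setdiff(elements, covered)
  parts <- c(
    lapply(maximal, function(s) {
      inner <- Filter(function(t) length(t) < length(s) && all(t %in% s), sides)
      newick_node(s, inner, labels)
    }),
    as.list(quote_label(labels[free]))
  )
  mins <- c(vapply(maximal, min, 0L), free)
  paste0("(", paste(unlist(parts)[order(mins)], collapse = ","), ")")
}

#' Does a tree set display every split of a system?
#'
#' A split is displayed by a tree set if at least one member tree has an edge
#' inducing it. Returns `TRUE` iff every split of `S` is displayed.
#'
#' @param ts A `"tree_set"` (or single `phylo`).
#' @param S A `"split_system"` on the same taxa set.
#' @return Logical.
#' @export
displays <- function(ts, S) {
  S <- split_system(S)
  if (inherits(ts, "phylo")) ts <- tree_set(ts, S$labels)
  stopifnot(inherits(ts, "tree_set"))
  if (!setequal(attr(ts, "taxa"), S$labels)) {
    stop("tree set and split system are on different taxa sets")
  }
  want <- vapply(S$sides, side_key, "")
  seen <- unique(unlist(lapply(unclass(ts), function(tr) {
    vapply(splits_of_tree(tr, S$labels)$sides, side_key, "")
  })))
  all(want %in% seen)
}

#' Union of the split systems of a set of trees
#'
#' @param ts A `"tree_set"`.
#' @return A `"split_system"` containing every split displayed by some tree.
#' @export
displayed_splits <- function(ts) {
  stopifnot(inherits(ts, "tree_set"))
  labels <- attr(ts, "taxa")
  sides <- unlist(lapply(unclass(ts), function(tr) {
    splits_of_tree(tr, labels)$sides
  }), recursive = FALSE)
  new_split_system(sides, labels)
}
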