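#' Validate and normalise a taxa set
#'
#' A taxa set is an ordered vector of distinct, non-empty labels; the order is
#' fixed and defines the 1-based index of each taxon. A single integer `x` is
#' shorthand for the labels `"1"`, ..., `"x"`.
#'
#' @param x A character vector of labels, or a single integer `n >= 2`.
#' @return A character vector of labels.
#' @examples
#' taxa_set(5)
#' taxa_set(c("Sulfolobus", "Methanococcus", "Haloferax"))
#' @export
taxa_set <- function(x) {
  if (is.numeric(x) && length(x) == 1L) {
    if (is.na(x) || x != as.integer(x)) stop("taxa count must be a whole number")
    x <- as.character(seq_len(as.integer(x)))
  }
  labels <- as.character(x)
  if (length(labels) < 2L) stop("a taxa set needs at least 2 taxa")
  if (anyNA(labels) || any(!nzchar(labels))) stop("taxon labels must be non-empty")
  if (anyDuplicated(labels)) {
    stop("duplicate taxon label: ", labels[duplicated(labels)][1L])
  }
  labels
}

# combn() treats a scalar x as seq_len(x); this keeps a length-1 vector literal
combn_list <- function(x, k) {
  if (length(x) == 1L) {
    if (k == 1L) return(list(x)) else return(list())
  }
  utils::combn(x, k, simplify = FALSE)
}

# Canonical internal form of a split: the sorted vector of taxon indices on the
# side NOT containing taxon 1. Two splits are equal iff their canonical sides
# are equal, which makes A|B and B|A the same object.
canonical_side <- function(idx, n) {
  idx <- sort(unique(as.integer(idx)))
  if (1L %in% idx) idx <- setdiff(seq_len(n), idx)
  idx
}

side_key <- function(side) paste(side, collapse = ",")

new_split <- function(side, labels) {
  structure(list(side = side, n = length(labels), labels = labels),
            class = "split")
}

#' Construct a split (bipartition) of a taxa set
#'
#' A split `A|B` is a bipartition of the taxa into two non-empty parts. The
#' split is stored canonically by the side not containing the first taxon, so
#' `make_split(A, X)` and `make_split(X \ A, X)` return the same object.
#'
#' @param members Labels (character) or 1-based indices (numeric) of one side.
#' @param taxa A taxa set (see [taxa_set()]).
#' @return An object of class `"split"`.
#' @examples
#' make_split(c(1, 2), taxa_set(5))          # the split 12|345
#' make_split(c(3, 4, 5), taxa_set(5))       # the same split
#' @export
make_split <- function(members, taxa) {
  labels <- taxa_set(taxa)
  n <- length(labels)
  if (length(members) == 0L) stop("split side is empty: both parts must be non-empty")
  if (is.character(members)) {
    idx <- match(members, labels)
    if (anyNA(idx)) stop("unknown taxon label: ", members[is.na(idx)][1L])
  } else {
    idx <- as.integer(members)
    if (anyNA(idx) || any(idx < 1L) || any(idx > n)) {
      stop("taxon index out of range 1..", n)
    }
  }
  idx <- sort(unique(idx))
  if (length(idx) == n) {
    stop("split side equals the taxa set: both parts must be non-empty")
  }
  new_split(canonical_side(idx, n), labels)
}

#' @export
print.split <- function(x, ...) {
  other <- setdiff(seq_len(x$n), x$side)
  cat(sprintf("Split on %d taxa (size %d%s): {%s} | {%s}\n",
              x$n, split_size(x), if (is_trivial_split(x)) ", trivial" else "",
              paste(x$labels[other], collapse = ","),
              paste(x$labels[x$side], collapse = ",")))
  invisible(x)
}

#' Size and triviality of a split
#'
#' The size of a split `A|B` is `min(|A|, |B|)`; a split of size 1 is trivial.
#'
#' @param s A `"split"` object.
#' @return `split_size()` an integer; `is_trivial_split()` a logical.
#' @export
split_size <- function(s) {
  stopifnot(inherits(s, "split"))
  min(length(s$side), s$n - length(s$side))
}

#' @rdname split_size
#' @export
is_trivial_split <- function(s) split_size(s) == 1L

same_taxa <- function(a, b) identical(a$labels, b$labels)

# Buneman four-intersection test on canonical sides (indices), given n.
sides_compatible <- function(a, b, n) {
  # a, b exclude taxon 1, so B∩D (complements) always contains 1; the test
  # reduces to: disjoint, or one nested in the other.
  i <- length(intersect(a, b))
  i == 0L || i == length(a) || i == length(b)
}

#' Buneman compatibility of two splits
#'
#' Splits `A|B` and `C|D` on the same taxa set are compatible iff at least one
#' of the four intersections `A∩C`, `A∩D`, `B∩C`, `B∩D` is empty. A split is
#' always compatible with itself.
#'
#' @param s1,s2 `"split"` objects on the same taxa set.
#' @return Logical.
#' @examples
#' X <- taxa_set(5)
#' are_compatible(make_split(1:2, X), make_split(2:3, X))  # FALSE
#' are_compatible(make_split(1:2, X), make_split(3:4, X))  # TRUE
#' @export
are_compatible <- function(s1, s2) {
  stopifnot(inherits(s1, "split"), inherits(s2, "split"))
  if (!same_taxa(s1, s2)) stop("splits are on different taxa sets")
  sides_compatible(s1$side, s2$side, s1$n)
}

new_split_system <- function(sides, labels) {
  keys <- vapply(sides, side_key, "")
  keep <- !duplicated(keys)
  sides <- sides[keep]
  # deterministic canonical order: by size of canonical side, then lexicographic
  ord <- order(lengths(sides), vapply(sides, function(s) {
    paste(sprintf("%05d", s), collapse = ",")
  }, ""))
  structure(list(labels = labels, sides = sides[ord]), class = "split_system")
}

#' Construct a split system
#'
#' A split system is a set of distinct splits over one taxa set. Member splits
#' may be given as `"split"` objects or as vectors of labels/indices naming one
#' side each; duplicates under canonical equality are removed.
#'
#' @param splits A list of `"split"` objects or of member vectors.
#' @param taxa A taxa set; may be omitted when `splits` are `"split"` objects.
#' @return An object of class `"split_system"`.
#' @examples
#' split_system(list(c(1, 2), c(2, 3), c(3, 4)), taxa_set(5))
#' @export
split_system <- function(splits = list(), taxa = NULL) {
  if (inherits(splits, "split_system")) return(splits)
  if (inherits(splits, "split")) splits <- list(splits)
  if (is.null(taxa)) {
    if (length(splits) == 0L || !inherits(splits[[1L]], "split")) {
      stop("taxa must be given unless splits are 'split' objects")
    }
    taxa <- splits[[1L]]$labels
  }
  labels <- taxa_set(taxa)
  sides <- lapply(splits, function(s) {
    if (inherits(s, "split")) {
      if (!identical(s$labels, labels)) stop("splits are on different taxa sets")
      s$side
    } else {
      make_split(s, labels)$side
    }
  })
  new_split_system(sides, labels)
}

#' @export
print.split_system <- function(x, ...) {
  cat(sprintf("Split system: %d split(s) on %d taxa (%d nontrivial)\n",
              length(x$sides), length(x$labels), length(nontrivial_sides(x))))
  shown <- utils::head(seq_along(x$sides), 12L)
  for (i in shown) cat(" ", format_side(x$sides[[i]], x$labels), "\n")
  if (length(x$sides) > length(shown)) {
    cat("  ... and", length(x$sides) - length(shown), "more\n")
  }
  invisible(x)
}

format_side <- function(side, labels) {
  n <- length(labels)
  other <- setdiff(seq_len(n), side)
  paste0(paste(labels[other], collapse = ","), " | ",
         paste(labels[side], collapse = ","))
}

#' Number of splits in a split system
#' @param S A `"split_system"`.
#' @return Integer count.
#' @export
n_splits <- function(S) {
  stopifnot(inherits(S, "split_system"))
  length(S$sides)
}

#' Extract the splits of a system as a list of `"split"` objects
#' @param S A `"split_system"`.
#' @param nontrivial Drop trivial splits first?
#' @return A list of `"split"` objects.
#' @export
system_splits <- function(S, nontrivial = FALSE) {
  stopifnot(inherits(S, "split_system"))
  sides <- if (nontrivial) nontrivial_sides(S) else S$sides
  lapply(sides, new_split, labels = S$labels)
}

# canonical sides of nontrivial member splits
nontrivial_sides <- function(S) {
  n <- length(S$labels)
  Filter(function(s) min(length(s), n - length(s)) > 1L, S$sides)
}

#' All splits on a taxa set
#'
#' Enumerates the full split set on `taxa`; there are `2^(n-1) - 1` splits
#' (each identified with its side not containing the first taxon).
#'
#' @param taxa A taxa set.
#' @param nontrivial Keep only splits of size at least 2?
#' @return A `"split_system"`.
#' @examples
#' n_splits(all_splits(taxa_set(5)))  # 15
#' @export
all_splits <- function(taxa, nontrivial = FALSE) {
  labels <- taxa_set(taxa)
  n <- length(labels)
  sides <- list()
  for (k in seq_len(n - 1L)) {
    if (nontrivial && (k < 2L || k > n - 2L)) next
    sides <- c(sides, combn_list(seq.int(2L, n), k))
  }
  new_split_system(sides, labels)
}

#' Is a split system pairwise compatible?
#'
#' True iff every unordered pair of member splits satisfies the Buneman
#' condition; vacuously true for empty and singleton systems. By the splits
#' equivalence theorem this is exactly the condition for the system (plus all
#' trivial splits) to be displayed by a single tree.
#'
#' @param S A `"split_system"`.
#' @return Logical.
#' @export
is_pairwise_compatible <- function(S) {
  stopifnot(inherits(S, "split_system"))
  is.null(first_incompatible_pair(S))
}

# first incompatible pair of canonical sides, or NULL
first_incompatible_pair <- function(S) {
  sides <- S$sides
  n <- length(S$labels)
  k <- length(sides)
  if (k < 2L) return(NULL)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      if (!sides_compatible(sides[[i]], sides[[j]], n)) return(c(i, j))
    }
  }
  NULL
}
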