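#' Read a SplitsTree-style NEXUS SPLITS file
#'
#' Parses the `TAXA` block (`DIMENSIONS NTAX`, `TAXLABELS`) and the `SPLITS`
#' block (`DIMENSIONS`, optional `FORMAT` with `labels`/`weights`/`confidences`
#' flags, optional `CYCLE`, and a `MATRIX` whose rows are
#' `[comment] weight i1 i2 ... ,` — the listed 1-based taxon indices form one
#' side of the split, the complement is inferred). The SplitsTree4 st_splits
#' dialect is accepted: bracketed comments, trailing commas, case-insensitive
#' keywords, `end;` or `endblock;`, quoted labels. Parse errors report the
#' offending line number.
#'
#' @param path Path to a NEXUS file.
#' @return An object of class `"splits_file_model"`: `system` (a
#'   `"split_system"`), `weights` (named by canonical split, aligned with
#'   `system$sides`), `cycle` (integer vector or `NULL`), `provenance`.
#' @export
read_nexus_splits <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^\\s*#NEXUS", lines[1L], ignore.case = TRUE)) {
    stop("line 1: not a NEXUS file (missing #NEXUS header)")
  }
  blk <- nexus_block(lines, "taxa")
  if (is.null(blk)) stop("no TAXA block found")
  labels <- parse_taxa_block(lines, blk)
  blk <- nexus_block(lines, "splits")
  if (is.null(blk)) stop("no SPLITS block found")
  model <- parse_splits_block(lines, blk, labels)
  model$provenance <- list(path = path, dialect = "splitstree-st_splits")
  model
}

# locate a "begin <name>; ... end;" block, returning c(first, last) line idx
nexus_block <- function(lines, name) {
  lo <- grep(paste0("^\\s*begin\\s+", name, "\\s*;"), lines, ignore.case = TRUE)
  if (!length(lo)) return(NULL)
  lo <- lo[1L]
  ends <- grep("^\\s*end(block)?\\s*;", lines, ignore.case = TRUE)
  hi <- ends[ends > lo]
  if (!length(hi)) stop("line ", lo, ": block '", name, "' is never closed")
  c(lo, hi[1L])
}

strip_comments <- function(x) gsub("\\[[^]]*\\]", " ", x)

nexus_tokens <- function(x) {
  x <- strip_comments(x)
  toks <- character(0)
  while (nchar(x <- sub("^\\s+", "", x))) {
    if (startsWith(x, "'")) {
      m <- regmatches(x, regexpr("^'([^']|'')*'", x))
      if (!length(m)) stop("unterminated quoted label")
      toks <- c(toks, gsub("''", "'", substr(m, 2L, nchar(m) - 1L)))
      x <- substr(x, nchar(m) + 1L, nchar(x))
    } else {
      m <- regmatches(x, regexpr("^[^\\s;,]+", x, perl = TRUE))
      toks <- c(toks, m)
      x <- substr(x, nchar(m) + 1L, nchar(x))
      x <- sub("^[;,]", "", x)
    }
  }
  toks
}

parse_taxa_block <- function(lines, blk) {
  rng <- seq.int(blk[1L], blk[2L])
  dim_i <- rng[grepl("^\\s*dimensions", lines[rng], ignore.case = TRUE)]
  if (!length(dim_i)) stop("line ", blk[1L], ": TAXA block has no DIMENSIONS")
  ntax <- parse_key_int(lines[dim_i[1L]], "ntax", dim_i[1L])
  lab_i <- rng[grepl("^\\s*taxlabels", lines[rng], ignore.case = TRUE)]
  if (!length(lab_i)) stop("line ", blk[1L], ": TAXA block has no TAXLABELS")
  buf <- character(0)
  i <- lab_i[1L]
  first <- sub("^\\s*taxlabels", "", lines[i], ignore.case = TRUE)
  repeat {
    chunk <- if (i == lab_i[1L]) first else lines[i]
    done <- grepl(";", strip_comments(chunk))
    buf <- c(buf, nexus_tokens(sub(";.*$", "", chunk)))
    if (done || i == blk[2L]) break
    i <- i + 1L
  }
  if (length(buf) != ntax) {
    stop("line ", lab_i[1L], ": expected ", ntax, " taxon labels, found ",
         length(buf))
  }
  taxa_set(buf)
}

parse_key_int <- function(line, key, lineno) {
  m <- regmatches(line, regexpr(paste0("(?i)", key, "\\s*=\\s*[0-9]+"), line,
                                perl = TRUE))
  if (!length(m)) stop("line ", lineno, ": missing ", toupper(key), "=")
  as.integer(sub(".*=\\s*", "", m))
}

parse_splits_block <- function(lines, blk, labels) {
  n <- length(labels)
  rng <- seq.int(blk[1L], blk[2L])
  dim_i <- rng[grepl("^\\s*dimensions", lines[rng], ignore.case = TRUE)]
  nsplits <- NA_integer_
  if (length(dim_i)) {
    d <- lines[dim_i[1L]]
    if (grepl("(?i)ntax\\s*=", d, perl = TRUE)) {
      ntax <- parse_key_int(d, "ntax", dim_i[1L])
      if (ntax != n) {
        stop("line ", dim_i[1L], ": SPLITS NTAX=", ntax,
             " does not match TAXA block (", n, ")")
      }
    }
    if (grepl("(?i)nsplits\\s*=", d, perl = TRUE)) {
      nsplits <- parse_key_int(d, "nsplits", dim_i[1L])
    }
  }
  weights_on <- TRUE
  fmt_i <- rng[grepl("^\\s*format", lines[rng], ignore.case = TRUE)]
  if (length(fmt_i)) {
    weights_on <- !grepl("(?i)weights\\s*=\\s*no", lines[fmt_i[1L]], perl = TRUE)
  }
  labels_on <- length(fmt_i) &&
    grepl("(?i)\\blabels\\s*=\\s*(yes|left|right)", lines[fmt_i[1L]], perl = TRUE)
  cycle <- NULL
  cyc_i <- rng[grepl("^\\s*cycle", lines[rng], ignore.case = TRUE)]
  if (length(cyc_i)) {
    toks <- nexus_tokens(sub("(?i)^\\s*cycle", "", lines[cyc_i[1L]], perl = TRUE))
    cycle <- as.integer(toks)
    if (anyNA(cycle) || !setequal(cycle, seq_len(n))) {
      stop("line ", cyc_i[1L], ": CYCLE must be a permutation of 1..", n)
    }
  }
  mat_i <- rng[grepl("^\\s*matrix\\s*$|^\\s*matrix\\b", lines[rng],
                     ignore.case = TRUE)]
  if (!length(mat_i)) stop("line ", blk[1L], ": SPLITS block has no MATRIX")
  sides <- list()
  weights <- numeric(0)
  keys <- character(0)
  i <- mat_i[1L] + 1L
  while (i < blk[2L]) {
    raw <- strip_comments(lines[i])
    if (grepl("^\\s*;\\s*$", raw)) break
    row <- sub(",\\s*$", "", sub(";\\s*$", "", raw))
    if (nchar(trimws(row))) {
      toks <- nexus_tokens(row)
      if (labels_on && length(toks)) toks <- toks[-1L]
      vals <- suppressWarnings(as.numeric(toks))
      if (anyNA(vals)) {
        stop("line ", i, ": non-numeric entry '", toks[is.na(vals)][1L],
             "' in SPLITS matrix")
      }
      if (weights_on) {
        if (length(vals) < 2L) stop("line ", i, ": expected a weight and at least one index")
        w <- vals[1L]
        if (w < 0) stop("line ", i, ": negative split weight")
        idx <- vals[-1L]
      } else {
        w <- 1.0
        idx <- vals
      }
      if (any(idx != round(idx)) || any(idx < 1) || any(idx > n)) {
        stop("line ", i, ": taxon index out of range 1..", n)
      }
      idx <- sort(unique(as.integer(idx)))
      if (length(idx) == n) stop("line ", i, ": side equals taxa set")
      if (length(idx) == 0L) stop("line ", i, ": empty side")
      side <- canonical_side(idx, n)
      key <- side_key(side)
      if (key %in% keys) {
        warning("line ", i, ": duplicate split collapsed (first weight kept)")
      } else {
        keys <- c(keys, key)
        sides <- c(sides, list(side))
        weights <- c(weights, w)
      }
    }
    i <- i + 1L
  }
  if (!is.na(nsplits) && length(keys) != nsplits) {
    warning("SPLITS matrix has ", length(keys),
            " distinct splits but NSPLITS=", nsplits)
  }
  system <- new_split_system(sides, labels)
  wmap <- stats::setNames(weights, keys)
  structure(list(system = system,
                 weights = unname(wmap[vapply(system$sides, side_key, "")]),
                 cycle = cycle, provenance = NULL),
            class = "splits_file_model")
}

#' @export
print.splits_file_model <- function(x, ...) {
  cat(sprintf("Splits file model: %d split(s) on %d taxa%s\n",
              length(x$system$sides), length(x$system$labels),
              if (!is.null(x$provenance$path))
                paste0(" [", x$provenance$path, "]") else ""))
  invisible(x)
}

#' Write a split system to a SplitsTree-style NEXUS file
#'
#' @param x A `"split_system"` or `"splits_file_model"`.
#' @param path Output file path.
#' @param weights Optional weights aligned with the system's splits
#'   (default 1, or the model's stored weights).
#' @return `path`, invisibly.
#' @export
write_nexus_splits <- function(x, path, weights = NULL) {
  if (inherits(x, "splits_file_model")) {
    if (is.null(weights)) weights <- x$weights
    x <- x$system
  }
  stopifnot(inherits(x, "split_system"))
  labels <- x$labels
  n <- length(labels)
  k <- length(x$sides)
  if (is.null(weights)) weights <- rep(1, k)
  stopifnot(length(weights) == k)
  out <- c(
    "#NEXUS",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", n),
    "  TAXLABELS",
    paste0("    ", paste(quote_nexus(labels), collapse = " ")),
    "  ;",
    "END;",
    "BEGIN SPLITS;",
    sprintf("  DIMENSIONS NTAX=%d NSPLITS=%d;", n, k),
    "  FORMAT labels=no weights=yes confidences=no;",
    "  MATRIX",
    vapply(seq_len(k), function(i) {
      sprintf("    [%d, size=%d] %s %s,", i,
              min(length(x$sides[[i]]), n - length(x$sides[[i]])),
              format(weights[i]), paste(x$sides[[i]], collapse = " "))
    }, ""),
    "  ;",
    "END;"
  )
  writeLines(out, path)
  invisible(path)
}

quote_nexus <- function(x) {
  needs <- grepl("[^A-Za-z0-9_.+-]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Read and write trees in Newick format
#'
#' `write_newick()` writes one tree per line with no branch lengths, rooted at
#' the interior vertex adjacent to the first taxon; `read_newick()` reads one
#' or more trees and suppresses any degree-2 root, so round trips preserve the
#' split system exactly.
#'
#' @param ts A `"tree_set"` or single `phylo` (for writing).
#' @param path File path.
#' @param taxa Optional taxa set fixing the index order on read; defaults to
#'   the first tree's tip labels.
#' @return `read_newick()` a `"tree_set"`; `write_newick()` `path`, invisibly.
#' @export
read_newick <- function(path, taxa = NULL) {
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop("no trees found in ", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, ape::collapse.singles)
  labels <- if (is.null(taxa)) taxa_set(trees[[1L]]$tip.label) else taxa_set(taxa)
  trees <- lapply(trees, function(tr) {
    if (length(tr$tip.label) > 3L && ape::is.rooted(tr)) ape::unroot(tr) else tr
  })
  tree_set(trees, labels)
}

#' @rdname read_newick
#' @export
write_newick <- function(ts, path) {
  if (inherits(ts, "phylo")) ts <- tree_set(ts)
  stopifnot(inherits(ts, "tree_set"))
  txt <- vapply(unclass(ts), function(tr) ape::write.tree(tr), "")
  writeLines(txt, path)
  invisible(path)
}

#' Read a plain-text split list
#'
#' One split per line, either `A|B` with comma- or space-separated labels on
#' both sides, or just the `A` side when the taxa are known — from a header
#' line `taxa: l1 l2 ...` or the `taxa` argument. Blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path File path.
#' @param taxa Optional taxa set (required for one-sided lines without a
#'   header).
#' @return A `"split_system"`.
#' @export
read_split_list <- function(path, taxa = NULL) {
  lines <- readLines(path, warn = FALSE)
  labels <- if (is.null(taxa)) NULL else taxa_set(taxa)
  sides <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nchar(ln) || startsWith(ln, "#")) next
    if (grepl("^taxa\\s*:", ln, ignore.case = TRUE)) {
      toks <- strsplit(sub("(?i)^taxa\\s*:\\s*", "", ln, perl = TRUE),
                       "[,[:space:]]+")[[1L]]
      labels <- taxa_set(toks[nzchar(toks)])
      next
    }
    parts <- strsplit(ln, "|", fixed = TRUE)[[1L]]
    a <- strsplit(trimws(parts[1L]), "[,[:space:]]+")[[1L]]
    a <- a[nzchar(a)]
    if (length(parts) > 2L) stop("line ", i, ": more than one '|'")
    if (length(parts) == 2L) {
      b <- strsplit(trimws(parts[2L]), "[,[:space:]]+")[[1L]]
      b <- b[nzchar(b)]
      if (is.null(labels)) labels <- taxa_set(c(a, b))
      if (!setequal(c(a, b), labels) || length(c(a, b)) != length(labels)) {
        stop("line ", i, ": sides do not bipartition the taxa set")
      }
    } else if (is.null(labels)) {
      stop("line ", i, ": one-sided split needs a 'taxa:' header or taxa argument")
    }
    side <- tryCatch(make_split(a, labels)$side,
                     error = function(e) stop("line ", i, ": ",
                                              conditionMessage(e), call. = FALSE))
    sides <- c(sides, list(side))
  }
  if (is.null(labels)) stop("no taxa and no splits found in ", path)
  new_split_system(sides, labels)
}
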