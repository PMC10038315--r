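#' Sibling matrix of a poset family
#'
#' The square matrix A with one row/column per species, where A(i, j) counts
#' the species strictly above s_j in the s_i-poset, and the diagonal holds
#' the sentinel -1. For a consistent family A is symmetric, and reading it as
#' an edge-labelled graph, maximal equal values identify sibling leaves: the
#' higher the count, the deeper the pair sits together in the tree.
#'
#' @param fam A [poset_family()].
#' @return An integer matrix of class `sibling_matrix` with species labels as
#'   dimnames and a `provenance` attribute mapping each current label to the
#'   original species it stands for (used once merged labels appear).
#' @examples
#' fam <- generate_posets(parse_newick("(((s1,s2),s3),(s4,s5));"))
#' build_matrix(fam)
#' @export
build_matrix <- function(fam) {
  stopifnot(inherits(fam, "poset_family"))
  labs <- sort(fam$species)
  n <- length(labs)
  a <- matrix(0L, n, n, dimnames = list(labs, labs))
  for (i in labs) {
    lesser <- fam$posets[[i]]$pairs[, 1L]
    counts <- table(lesser)
    a[i, names(counts)] <- as.integer(counts)
  }
  diag(a) <- -1L
  new_sibling_matrix(a, stats::setNames(as.list(labs), labs))
}

new_sibling_matrix <- function(a, provenance) {
  structure(a, provenance = provenance, class = c("sibling_matrix", "matrix"))
}

#' @export
print.sibling_matrix <- function(x, ...) {
  print(unclass_matrix(x))
  invisible(x)
}

unclass_matrix <- function(a) {
  attr(a, "provenance") <- NULL
  class(a) <- NULL
  a
}

#' Validate a sibling matrix
#'
#' A sibling matrix derived from a consistent family must be symmetric;
#' asymmetry signals mutually inconsistent posets, from which no tree can be
#' reconstructed.
#'
#' @param a A `sibling_matrix`.
#' @return TRUE iff `a[i, j] == a[j, i]` for all i, j.
#' @export
validate_matrix <- function(a) {
  isTRUE(all(a == t(unclass_matrix(a))))
}

#' Maximum off-diagonal entry
#'
#' The current sibling signal: the largest off-diagonal value of the matrix
#' (0 when everything off-diagonal is 0, which is the termination state of
#' tree construction).
#'
#' @param a A `sibling_matrix` with at least two rows.
#' @return A non-negative integer.
#' @export
find_max <- function(a) {
  if (nrow(a) < 2L) {
    phgt_stop("sibling matrix smaller than 2x2 has no off-diagonal maximum",
              "degenerate_input_error")
  }
  m <- unclass_matrix(a)
  diag(m) <- NA_integer_
  max(m, na.rm = TRUE)
}

#' Sibling groups at the current maximum
#'
#' Builds the graph whose edges join labels with matrix value equal to `max`
#' and returns its connected components (each with two or more members) as
#' the sibling groups of this round. A component that is a clique is a plain
#' sibling set; a connected non-clique component (a star) is still returned
#' whole -- all its labels become children of a single new parent -- with a
#' notice, since equal closeness to a shared hub with no closer partner
#' admits no finer grouping.
#'
#' @param a A `sibling_matrix`.
#' @param max The value returned by [find_max()]; must be positive.
#' @return A list of character vectors of labels, ordered by the smallest
#'   original species label each contains.
#' @export
find_sibling_groups <- function(a, max = find_max(a)) {
  stopifnot(max > 0L)
  labs <- rownames(a)
  adj <- unclass_matrix(a) == max
  diag(adj) <- FALSE
  groups <- list()
  unseen <- labs
  while (length(unseen) > 0L) {
    comp <- unseen[1L]
    frontier <- comp
    while (length(frontier) > 0L) {
      nb <- labs[Reduce(`|`, lapply(frontier, function(l) adj[l, ]))]
      nb <- setdiff(nb, comp)
      comp <- c(comp, nb)
      frontier <- nb
    }
    unseen <- setdiff(unseen, comp)
    if (length(comp) >= 2L) {
      sub <- adj[comp, comp, drop = FALSE]
      diag(sub) <- TRUE
      if (!all(sub)) {
        phgt_note("non-clique sibling component {",
                  paste(sort(comp), collapse = ", "),
                  "}: grouping all members under one parent")
      }
      groups <- c(groups, list(sort(comp)))
    }
  }
  prov <- attr(a, "provenance")
  first <- vapply(groups,
                  function(g) min(unlist(prov[g], use.names = FALSE)),
                  character(1))
  groups[order(first)]
}

#' Merge a sibling group in matrix and forest
#'
#' Replaces the rows/columns of a sibling group by a single merged label and
#' records the grouping in the growing forest: the group's subtrees gain a
#' common parent. For every outside label, the group members must agree on
#' their matrix value towards it; disagreement means the posets are mutually
#' inconsistent and tree construction fails.
#'
#' @param a A `sibling_matrix`.
#' @param group A character vector of current labels (from
#'   [find_sibling_groups()]).
#' @param forest Named list of subtrees (internal node structures), one per
#'   current label.
#' @return A list with the reduced `matrix` and the updated `forest`.
#' @export
merge_siblings <- function(a, group, forest) {
  labs <- rownames(a)
  stopifnot(all(group %in% labs), all(group %in% names(forest)))
  outside <- setdiff(labs, group)
  vals <- unclass_matrix(a)[group, outside, drop = FALSE]
  if (length(outside) > 0L) {
    agree <- apply(vals, 2L, function(col) length(unique(col)) == 1L)
    if (!all(agree)) {
      w <- outside[which(!agree)[1L]]
      phgt_stop(sprintf(
        "inconsistent posets: sibling group {%s} disagrees towards %s (%s)",
        paste(group, collapse = ", "), w,
        paste(vals[, w], collapse = " vs ")),
        "inconsistency_error")
    }
  }
  prov <- attr(a, "provenance")
  merged_species <- sort(unlist(prov[group], use.names = FALSE))
  new_lab <- paste0("<", paste(merged_species, collapse = ","), ">")
  if (length(outside) > 0L) {
    keep <- unclass_matrix(a)[outside, outside, drop = FALSE]
    row <- vals[1L, , drop = TRUE]
    m <- rbind(cbind(keep, row), c(row, -1L))
  } else {
    m <- matrix(-1L, 1L, 1L)
  }
  dimnames(m) <- list(c(outside, new_lab), c(outside, new_lab))
  storage.mode(m) <- "integer"
  prov <- c(prov[outside], stats::setNames(list(merged_species), new_lab))
  forest[[new_lab]] <- internal_node(unname(forest[group]))
  forest <- forest[c(outside, new_lab)]
  list(matrix = new_sibling_matrix(m, prov), forest = forest)
}

#' Reconstruct the species tree from a poset family
#'
#' The tree-construction algorithm: build the sibling matrix, check symmetry,
#' and repeatedly (i) find the maximum off-diagonal value, (ii) collect the
#' sibling groups it defines, (iii) merge each group's rows/columns and give
#' its subtrees a common parent -- until the maximum reaches 0, at which
#' point one root adopts all remaining subtrees. Fails with an inconsistency
#' error when the matrix is asymmetric or a merge finds disagreeing counts
#' (missing or incorrect poset data).
#'
#' @param fam A [poset_family()].
#' @return An `stree` compatible with every poset in the family.
#' @examples
#' t <- parse_newick("(((s1,s2),s3),(s4,s5));")
#' stree_equal(construct_tree(generate_posets(t)), t)
#' @export
construct_tree <- function(fam) {
  a <- build_matrix(fam)
  if (!validate_matrix(a)) {
    phgt_stop(sprintf(
      "inconsistent posets for gene '%s': sibling matrix is asymmetric",
      fam$gene), "inconsistency_error")
  }
  labs <- rownames(a)
  forest <- stats::setNames(lapply(labs, leaf_node), labs)
  if (length(labs) > 1L) {
    while ((mx <- find_max(a)) > 0L) {
      for (group in find_sibling_groups(a, mx)) {
        merged <- merge_siblings(a, group, forest)
        a <- merged$matrix
        forest <- merged$forest
      }
      if (nrow(a) == 1L) break
    }
  }
  root <- if (length(forest) == 1L) forest[[1L]] else
    internal_node(unname(forest))
  t <- new_stree(root, fam$species)
  if (!setequal(species_set(t), fam$species)) {
    phgt_stop("constructed tree does not cover the species set",
              "inconsistency_error")
  }
  t
}
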