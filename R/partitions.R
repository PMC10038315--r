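#' 2-partitions of a species set
#'
#' Cutting any edge of a rooted tree splits the leaves into two nonempty
#' sets; these edge-induced bipartitions are the currency in which trees are
#' compared. A 2-partition is stored in canonical form: both sides sorted,
#' sides ordered by (size, smallest member), so equal partitions have equal
#' representations.
#'
#' @param side1,side2 Character vectors; disjoint, nonempty, jointly covering
#'   the underlying set.
#' @return An object of class `two_partition`: a list of the two sides.
#' @export
two_partition <- function(side1, side2) {
  side1 <- sort(unique(side1))
  side2 <- sort(unique(side2))
  if (length(side1) == 0L || length(side2) == 0L ||
      length(intersect(side1, side2)) > 0L) {
    phgt_stop("2-partition sides must be disjoint and nonempty",
              "domain_error")
  }
  swap <- length(side2) < length(side1) ||
    (length(side2) == length(side1) && side2[1L] < side1[1L])
  if (swap) { tmp <- side1; side1 <- side2; side2 <- tmp }
  structure(list(side1, side2), class = "two_partition")
}

#' @export
print.two_partition <- function(x, ...) {
  cat("{", paste(x[[1L]], collapse = ","), "} | {",
      paste(x[[2L]], collapse = ","), "}\n", sep = "")
  invisible(x)
}

partition_key <- function(p) {
  paste(paste(p[[1L]], collapse = ","), paste(p[[2L]], collapse = ","),
        sep = "|")
}

partition_universe <- function(p) sort(c(p[[1L]], p[[2L]]))

#' Edge-induced 2-partitions of a tree
#'
#' One 2-partition per edge: the species under the edge's child node versus
#' the rest. With `augment = TRUE`, a reserved pseudo-species `s0` is first
#' attached as an extra child of the root, which keeps the two sides of
#' root-adjacent edges distinguishable when partition sets of different trees
#' are united (the device used by the refinement algorithm). The returned set
#' is deduplicated in canonical form.
#'
#' @param t An `stree` with at least two leaves.
#' @param augment Attach the reserved root child `s0` first?
#' @return A list of [two_partition()] objects.
#' @export
find_two_partitions <- function(t, augment = FALSE) {
  stopifnot(inherits(t, "stree"))
  root <- t$root
  if (augment) {
    if ("s0" %in% t$species) {
      phgt_stop("species set already contains the reserved label s0",
                "label_collision_error")
    }
    root <- internal_node(c(root$children %||% list(root), list(leaf_node("s0"))))
  }
  full <- sort(node_species(root))
  out <- list()
  keys <- character(0)
  walk <- function(node) {
    for (child in node$children) {
      side <- node_species(child)
      p <- two_partition(side, setdiff(full, side))
      k <- partition_key(p)
      if (!k %in% keys) {
        keys <<- c(keys, k)
        out[[length(out) + 1L]] <<- p
      }
      if (!is_leaf_node(child)) walk(child)
    }
  }
  if (is_leaf_node(root)) {
    phgt_stop("a single-leaf tree induces no 2-partition",
              "degenerate_input_error")
  }
  walk(root)
  out
}

#' Do two 2-partitions contradict?
#'
#' Two 2-partitions X = {X1, X2} and Y = {Y1, Y2} of the same set contradict
#' when a crossing quadruple exists: species a, b in X1 and c, d in X2 with
#' a, c in Y1 and b, d in Y2. Equivalently, all four pairwise side
#' intersections are nonempty.
#'
#' @param x,y [two_partition()] objects over the same species set.
#' @return TRUE iff the partitions contradict.
#' @export
partitions_contradict <- function(x, y) {
  if (!identical(partition_universe(x), partition_universe(y))) {
    phgt_stop("2-partitions over different species sets", "domain_error")
  }
  all(length(intersect(x[[1L]], y[[1L]])) > 0L,
      length(intersect(x[[1L]], y[[2L]])) > 0L,
      length(intersect(x[[2L]], y[[1L]])) > 0L,
      length(intersect(x[[2L]], y[[2L]])) > 0L)
}

#' Do two trees contradict?
#'
#' Trees over the same leaf set contradict when some edge-induced 2-partition
#' of one contradicts some 2-partition of the other. Contradiction between
#' gene trees is the evidence from which horizontal transfer is inferred.
#'
#' @param t1,t2 `stree` objects with identical leaf sets.
#' @param all_witnesses Collect every contradicting partition pair instead of
#'   stopping at the first?
#' @return A logical verdict with attribute `witnesses`: a list of
#'   `list(p1 =, p2 =)` contradicting partition pairs (empty when
#'   compatible).
#' @export
trees_contradict <- function(t1, t2, all_witnesses = FALSE) {
  stopifnot(inherits(t1, "stree"), inherits(t2, "stree"))
  if (!setequal(t1$species, t2$species)) {
    phgt_stop("trees have different leaf sets", "domain_error")
  }
  if (length(t1$species) < 2L) {
    return(structure(FALSE, witnesses = list()))
  }
  q1 <- find_two_partitions(t1)
  q2 <- find_two_partitions(t2)
  witnesses <- list()
  for (p1 in q1) {
    if (length(p1[[1L]]) < 2L) next  # a singleton side cannot host a quadruple
    for (p2 in q2) {
      if (length(p2[[1L]]) < 2L) next
      if (partitions_contradict(p1, p2)) {
        witnesses[[length(witnesses) + 1L]] <- list(p1 = p1, p2 = p2)
        if (!all_witnesses) {
          return(structure(TRUE, witnesses = witnesses))
        }
      }
    }
  }
  structure(length(witnesses) > 0L, witnesses = witnesses)
}

#' Rebuild a tree from its (augmented) 2-partition set
#'
#' Inverse of [find_two_partitions()] with `augment = TRUE`. Partitions with
#' a singleton side carry no grouping information and are dropped; then,
#' repeatedly, the unprocessed partition whose non-`s0` side has minimum
#' cardinality (ties broken lexicographically on the sorted members) has that
#' side's members made siblings under a new node, which substitutes for them
#' in every remaining side. When all partitions are consumed, a root adopts
#' the remaining nodes and the `s0` leaf is stripped.
#'
#' @param q A list of [two_partition()] objects over the `s0`-augmented
#'   species set, mutually non-contradictory.
#' @return An `stree` over the species set without `s0`.
#' @export
construct_tree_from_partitions <- function(q) {
  if (length(q) == 0L) {
    phgt_stop("empty 2-partition set", "domain_error")
  }
  for (i in seq_along(q)) {
    for (j in seq_len(i - 1L)) {
      if (partitions_contradict(q[[i]], q[[j]])) {
        phgt_stop("2-partition set contradicts itself",
                  "contradiction_error",
                  witness = list(p1 = q[[j]], p2 = q[[i]]))
      }
    }
  }
  universe <- partition_universe(q[[1L]])
  if (!"s0" %in% universe) {
    phgt_stop("expected an s0-augmented 2-partition set", "domain_error")
  }
  labels <- universe
  forest <- stats::setNames(lapply(labels, leaf_node), labels)
  # keep only the non-s0 ("inner") side of each informative partition
  sides <- lapply(q, function(p) if ("s0" %in% p[[1L]]) p[[2L]] else p[[1L]])
  sides <- sides[vapply(sides, length, integer(1)) >= 2L]
  counter <- 0L
  while (length(sides) > 0L) {
    sizes <- vapply(sides, length, integer(1))
    keyed <- vapply(sides, function(s) paste(s, collapse = ","), character(1))
    pick <- order(sizes, keyed)[1L]
    group <- sides[[pick]]
    sides <- sides[-pick]
    if (!all(group %in% labels)) {
      phgt_stop("2-partition side references a label already consumed",
                "contradiction_error")
    }
    counter <- counter + 1L
    new_lab <- paste0("<u", counter, ">")
    forest[[new_lab]] <- internal_node(unname(forest[group]))
    forest[group] <- NULL
    labels <- c(setdiff(labels, group), new_lab)
    sides <- lapply(sides, function(s) {
      inside <- group %in% s
      if (!any(inside)) return(s)
      if (!all(inside)) {
        phgt_stop("2-partition sides cross: set is contradictory",
                  "contradiction_error")
      }
      sort(c(setdiff(s, group), new_lab))
    })
    keyed <- vapply(sides, function(s) paste(s, collapse = ","), character(1))
    sides <- sides[!duplicated(keyed)]
    sides <- sides[vapply(sides, length, integer(1)) >= 2L]
  }
  kids <- unname(forest[labels])
  root <- if (length(kids) == 1L) kids[[1L]] else internal_node(kids)
  strip_s0(new_stree(root, setdiff(universe, "s0")))
}

strip_s0 <- function(t) {
  drop <- function(node) {
    if (is_leaf_node(node)) return(node)
    kids <- Filter(function(k) !(is_leaf_node(k) && k$label == "s0"),
                   node$children)
    kids <- lapply(kids, drop)
    if (length(kids) == 1L) return(kids[[1L]])
    internal_node(kids)
  }
  new_stree(drop(t$root))
}

#' Minimum common refinement of two trees
#'
#' Two non-contradictory trees over the same leaf set always admit a common
#' refinement; the minimum one is obtained by uniting their `s0`-augmented
#' 2-partition sets and rebuilding a tree from the union. The result's
#' partition set equals that union, and the result is a refinement of both
#' inputs. Contradictory inputs raise an error naming witness partitions.
#'
#' @param t1,t2 `stree` objects over the same leaf set.
#' @return An `stree`, the minimum common refinement.
#' @examples
#' t1 <- parse_newick("((s1,s2),s3,s4);")
#' t2 <- parse_newick("((s1,s2),(s3,s4));")
#' write_newick(min_common_refinement(t1, t2))
#' @export
min_common_refinement <- function(t1, t2) {
  verdict <- trees_contradict(t1, t2)
  if (isTRUE(as.logical(verdict))) {
    w <- attr(verdict, "witnesses")[[1L]]
    phgt_stop(sprintf(
      "trees contradict: %s vs %s",
      partition_key(w$p1), partition_key(w$p2)),
      "contradiction_error", witness = w)
  }
  q <- c(find_two_partitions(t1, augment = TRUE),
         find_two_partitions(t2, augment = TRUE))
  q <- q[!duplicated(vapply(q, partition_key, character(1)))]
  construct_tree_from_partitions(q)
}
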