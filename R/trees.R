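#' Rooted species trees
#'
#' An S-tree is a rooted tree whose leaves are bijectively labelled by the
#' species set and whose internal nodes all have outdegree at least two. The
#' framework is purely topological: branch lengths are accepted on input and
#' discarded. Trees are treated as unordered; the canonical form sorts the
#' children of every node by the smallest species label beneath them, and all
#' equality comparisons are made in that form.
#'
#' @name stree
NULL

is_leaf_node <- function(node) !is.null(node$label)

leaf_node <- function(label) list(label = label)

internal_node <- function(children) list(children = children)

node_species <- function(node) {
  if (is_leaf_node(node)) return(node$label)
  unlist(lapply(node$children, node_species), use.names = FALSE)
}

canonicalize_node <- function(node) {
  if (is_leaf_node(node)) return(node)
  kids <- lapply(node$children, canonicalize_node)
  mins <- vapply(kids, function(k) min(node_species(k)), character(1))
  internal_node(kids[order(mins)])
}

new_stree <- function(root, species = NULL) {
  root <- canonicalize_node(root)
  structure(list(root = root,
                 species = sort(species %||% node_species(root))),
            class = "stree")
}

stree_check <- function(t) {
  leaves <- node_species(t$root)
  if (anyDuplicated(leaves)) {
    phgt_stop(paste0("duplicate leaf label(s): ",
                     paste(unique(leaves[duplicated(leaves)]), collapse = ", ")),
              "parse_error")
  }
  check_outdeg <- function(node) {
    if (is_leaf_node(node)) return(invisible(TRUE))
    if (length(node$children) < 2L) {
      phgt_stop("internal node with outdegree < 2", "domain_error")
    }
    for (k in node$children) check_outdeg(k)
    invisible(TRUE)
  }
  check_outdeg(t$root)
  invisible(t)
}

#' Parse a rooted tree from Newick text
#'
#' Reads a rooted Newick string (leaf labels required; internal labels and
#' branch lengths are ignored). Chains of outdegree-1 nodes are collapsed
#' with a notice. Duplicate leaf labels or malformed text raise a parse
#' error.
#'
#' @param text A Newick string ending in `;`, or a path to a file holding
#'   one.
#' @return An object of class `stree`.
#' @examples
#' parse_newick("((s1,s2),s3);")
#' @export
parse_newick <- function(text) {
  if (length(text) == 1L && !grepl(";", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  text <- gsub("[[:space:]]+", "", paste(text, collapse = ""))
  if (!nzchar(text) || !grepl(";", text)) {
    phgt_stop("malformed Newick: missing terminating ';'", "parse_error")
  }
  # trivial one-leaf tree, which ape does not represent
  if (grepl("^[A-Za-z0-9_.-]+(:[0-9.eE+-]+)?;$", text)) {
    lab <- sub("^([A-Za-z0-9_.-]+).*$", "\\1", text)
    return(new_stree(leaf_node(lab)))
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo")) {
    phgt_stop("malformed Newick input", "parse_error")
  }
  if (!is.null(phy$Nnode) && phy$Nnode > 0L) {
    deg <- tabulate(phy$edge[, 1L])
    if (any(deg[deg > 0L] == 1L)) {
      phgt_note("collapsing outdegree-1 chain(s) in Newick input")
      phy <- ape::collapse.singles(phy)
    }
  }
  t <- new_stree(phylo_to_node(phy))
  stree_check(t)
}

phylo_to_node <- function(phy) {
  ntip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  build <- function(id) {
    if (id <= ntip) return(leaf_node(phy$tip.label[id]))
    internal_node(lapply(kids[[as.character(id)]], build))
  }
  build(ntip + 1L)
}

node_to_newick <- function(node) {
  if (is_leaf_node(node)) return(node$label)
  paste0("(", paste(vapply(node$children, node_to_newick, character(1)),
                    collapse = ","), ")")
}

#' Write canonical Newick
#'
#' Serializes an `stree` in canonical form (children sorted by the smallest
#' species label they contain, no branch lengths), so that equal trees yield
#' identical strings.
#'
#' @param t An `stree`.
#' @return A Newick string ending in `;`.
#' @export
write_newick <- function(t) {
  stopifnot(inherits(t, "stree"))
  paste0(node_to_newick(t$root), ";")
}

#' @export
print.stree <- function(x, ...) {
  cat("rooted S-tree on", length(x$species), "species:", write_newick(x), "\n")
  invisible(x)
}

#' Tree equality up to child order
#'
#' @param t1,t2 `stree` objects.
#' @return TRUE when the two trees have the same topology and leaf labels.
#' @export
stree_equal <- function(t1, t2) {
  identical(write_newick(t1), write_newick(t2))
}

# Path of nodes from the root down to the given leaf label (inclusive).
path_to_leaf <- function(node, label, acc = list()) {
  acc <- c(acc, list(node))
  if (is_leaf_node(node)) {
    if (identical(node$label, label)) return(acc)
    return(NULL)
  }
  for (k in node$children) {
    got <- path_to_leaf(k, label, acc)
    if (!is.null(got)) return(got)
  }
  NULL
}

#' Most recent common ancestor
#'
#' Returns the subtree rooted at the most recent common ancestor of two
#' leaves; `stree_mrca(t, u, u)` is the leaf itself. The depth of that node
#' (root at depth 0) is attached as attribute `depth`.
#'
#' @param t An `stree`.
#' @param u,v Leaf labels.
#' @return An `stree` for the subtree rooted at the MRCA, with attribute
#'   `depth`.
#' @export
stree_mrca <- function(t, u, v) {
  stopifnot(inherits(t, "stree"))
  pu <- path_to_leaf(t$root, u)
  pv <- path_to_leaf(t$root, v)
  if (is.null(pu) || is.null(pv)) {
    phgt_stop(paste0("leaf not in tree: ", if (is.null(pu)) u else v),
              "lookup_error")
  }
  d <- 0L
  while (d + 1L <= min(length(pu), length(pv)) &&
         identical(pu[[d + 1L]], pv[[d + 1L]])) {
    d <- d + 1L
  }
  sub <- new_stree(pu[[d]])
  attr(sub, "depth") <- d - 1L
  sub
}

#' Species set of a tree or subtree
#'
#' The set of leaf labels beneath a node; for the whole tree this is the
#' species set S.
#'
#' @param t An `stree` (typically a subtree returned by [stree_mrca()]).
#' @return Sorted character vector of species labels.
#' @export
species_set <- function(t) {
  stopifnot(inherits(t, "stree"))
  sort(node_species(t$root))
}

# Locate the internal node whose species set equals `at` (exactly one exists
# per tree when it exists at all).
find_node_by_species <- function(node, at) {
  sp <- sort(node_species(node))
  if (identical(sp, sort(at))) return(node)
  if (is_leaf_node(node)) return(NULL)
  for (k in node$children) {
    got <- find_node_by_species(k, at)
    if (!is.null(got)) return(got)
  }
  NULL
}

#' Single refinement step
#'
#' Refines a multifurcation: at the internal node whose species set is `at`,
#' a new internal node is inserted as a child, adopting the subset of the
#' node's children that together cover exactly the species in `group`. The
#' adopted children must be a proper subset of at least two children, so both
#' nodes keep outdegree two or more.
#'
#' @param t An `stree`.
#' @param group Character vector of species covered exactly by the children
#'   to group.
#' @param at Species set identifying the internal node to refine; defaults to
#'   the whole species set (the root).
#' @return The refined `stree`.
#' @examples
#' refine_step(parse_newick("(s1,s2,s3);"), c("s1", "s2"))
#' @export
refine_step <- function(t, group, at = t$species) {
  stopifnot(inherits(t, "stree"))
  rebuild <- function(node) {
    if (is_leaf_node(node)) return(node)
    sp <- sort(node_species(node))
    if (identical(sp, sort(at))) {
      sets <- lapply(node$children, node_species)
      inside <- vapply(sets, function(s) all(s %in% group), logical(1))
      covered <- sort(unlist(sets[inside]))
      if (!setequal(covered, group)) {
        phgt_stop("group does not align with whole child subtrees",
                  "invalid_refinement_error")
      }
      if (sum(inside) < 2L) {
        phgt_stop("refinement group must cover at least two children",
                  "invalid_refinement_error")
      }
      if (all(inside)) {
        phgt_stop("refinement group must be a proper subset of the children",
                  "invalid_refinement_error")
      }
      y <- internal_node(node$children[inside])
      return(internal_node(c(node$children[!inside], list(y))))
    }
    internal_node(lapply(node$children, rebuild))
  }
  target <- find_node_by_species(t$root, at)
  if (is.null(target) || is_leaf_node(target)) {
    phgt_stop("no internal node with the given species set", "lookup_error")
  }
  new_stree(rebuild(t$root), t$species)
}

# For a focal leaf, the closeness level of every species: 0 for the focal
# leaf itself, then k for species first contributed by the k-th node on the
# walk from the leaf towards the root. Species within a level are equally
# close to the focal species.
focal_levels <- function(t, focal) {
  path <- path_to_leaf(t$root, focal)
  if (is.null(path)) {
    phgt_stop(paste0("leaf not in tree: ", focal), "lookup_error")
  }
  lv <- stats::setNames(integer(length(t$species)), sort(t$species))
  seen <- character(0)
  level <- 0L
  for (node in rev(path)) {
    fresh <- setdiff(node_species(node), seen)
    lv[fresh] <- level
    seen <- c(seen, fresh)
    level <- level + 1L
  }
  lv
}

#' Poset--tree compatibility
#'
#' A focal poset is compatible with a tree when every closeness statement it
#' makes is realised by the tree's MRCA structure: if j is at least as close
#' to the focal species i as k is, the MRCA of i and k must be at most as
#' deep as the MRCA of i and j (equivalently, the path from i or j to k
#' passes through MRCA(i, j)).
#'
#' @param p A [poset()].
#' @param t An `stree` over the same species set.
#' @return A list with `compatible` (logical) and, on failure, `violation`,
#'   the first violating triple `c(focal, j, k)`.
#' @export
is_compatible <- function(p, t) {
  stopifnot(inherits(p, "poset"), inherits(t, "stree"))
  if (!setequal(p$species, t$species)) {
    phgt_stop("poset and tree have different species sets", "domain_error")
  }
  lv <- focal_levels(t, p$focal)
  m <- p$pairs[p$pairs[, 1L] != p$focal, , drop = FALSE]
  for (r in seq_len(nrow(m))) {
    if (lv[m[r, 2L]] < lv[m[r, 1L]]) {
      return(list(compatible = FALSE,
                  violation = unname(c(p$focal, m[r, 1L], m[r, 2L]))))
    }
  }
  list(compatible = TRUE, violation = NULL)
}
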