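# Independent brute-force oracles used to validate the operational
# definitions in the package. These deliberately avoid the implementation's
# own shortcuts (level comparisons, intersection tests).

# Literal path-walking compatibility check: for each strict pair (j, k) of
# the focal poset, the unique tree path from the focal leaf to k must pass
# through the node MRCA(focal, j): k may not branch off strictly below the
# junction of the focal leaf and j (which is what "j is at least as close as
# k" means on a tree). The j-to-k path variant is uninformative: it passes
# the junction whenever k sits on the focal side, so it constrains nothing.
oracle_compatible <- function(p, t) {
  node_id_paths <- function(t) {
    paths <- list()
    walk <- function(node, acc) {
      acc <- c(acc, paste(sort(posetHGT:::node_species(node)),
                          collapse = ","))
      if (posetHGT:::is_leaf_node(node)) {
        paths[[node$label]] <<- acc
        return(invisible())
      }
      for (k in node$children) walk(k, acc)
    }
    walk(t$root, character(0))
    paths
  }
  paths <- node_id_paths(t)
  leaf_path_nodes <- function(u, v) {
    # node ids on the unique path between leaves u and v
    pu <- paths[[u]]; pv <- paths[[v]]
    d <- 0L
    while (d + 1L <= min(length(pu), length(pv)) &&
           identical(pu[d + 1L], pv[d + 1L])) d <- d + 1L
    c(pu[d:length(pu)], pv[d:length(pv)])
  }
  mrca_id <- function(u, v) {
    pu <- paths[[u]]; pv <- paths[[v]]
    common <- pu[seq_len(min(length(pu), length(pv)))] ==
      pv[seq_len(min(length(pu), length(pv)))]
    pu[max(which(common))]
  }
  m <- p$pairs[p$pairs[, 1L] != p$focal, , drop = FALSE]
  for (r in seq_len(nrow(m))) {
    j <- m[r, 1L]; k <- m[r, 2L]
    anc <- mrca_id(p$focal, j)
    if (!anc %in% leaf_path_nodes(p$focal, k)) return(FALSE)
  }
  TRUE
}

# Exhaustive quadruple enumeration for contradicting 2-partitions.
oracle_partitions_contradict <- function(x, y) {
  sp <- sort(c(x[[1L]], x[[2L]]))
  side_of <- function(p, s) if (s %in% p[[1L]]) 1L else 2L
  for (a in sp) for (b in sp) for (cc in sp) for (d in sp) {
    if (length(unique(c(a, b, cc, d))) < 4L) next
    if (side_of(x, a) == side_of(x, b) && side_of(x, cc) == side_of(x, d) &&
        side_of(x, a) != side_of(x, cc) &&
        side_of(y, a) == side_of(y, cc) && side_of(y, b) == side_of(y, d) &&
        side_of(y, a) != side_of(y, b)) {
      return(TRUE)
    }
  }
  FALSE
}

# Random contraction of a tree: collapse each non-root internal node into
# its parent with probability prob (so the result is a coarsening that the
# original refines).
contract_tree <- function(t, prob = 0.5) {
  collapse_children <- function(node) {
    out <- list()
    for (k in node$children) {
      if (posetHGT:::is_leaf_node(k)) {
        out <- c(out, list(k))
        next
      }
      kk <- posetHGT:::internal_node(collapse_children(k))
      if (stats::runif(1) < prob) {
        out <- c(out, kk$children)  # splice grandchildren into parent
      } else {
        out <- c(out, list(kk))
      }
    }
    out
  }
  if (posetHGT:::is_leaf_node(t$root)) return(t)
  posetHGT:::new_stree(posetHGT:::internal_node(collapse_children(t$root)),
                       t$species)
}

partition_keyset <- function(q) {
  sort(vapply(q, posetHGT:::partition_key, character(1)))
}

fig12_tree <- function() parse_newick("(((s1,s2),s3),(s4,s5));")

paper_family_4sp <- function() {
  S <- paste0("s", 1:4)
  poset_family("g1", list(
    poset("s1", list(c("s1", "s2"), c("s1", "s3"), c("s1", "s4"),
                     c("s2", "s4"), c("s3", "s4")), S),
    poset("s2", list(c("s2", "s1"), c("s2", "s3"), c("s2", "s4"),
                     c("s1", "s4"), c("s3", "s4")), S),
    poset("s3", list(c("s3", "s1"), c("s3", "s2"), c("s3", "s4"),
                     c("s1", "s4"), c("s2", "s4")), S),
    poset("s4", list(c("s4", "s1"), c("s4", "s2"), c("s4", "s3")), S)))
}

# Draw a transfer pair whose leaf regraft provably contradicts the base tree
# (uses the current RNG stream; deterministic under a fixed seed).
draw_transfer <- function(base) {
  sp <- base$species
  repeat {
    pick <- sample(sp, 2L)
    moved <- inject_hgt(base, pick[1L], pick[2L])
    if (isTRUE(as.logical(trees_contradict(moved, base)))) return(pick)
  }
}

expect_pairs_setequal <- function(pairs_matrix, expected_list) {
  got <- sort(paste(pairs_matrix[, 1L], pairs_matrix[, 2L]))
  want <- sort(vapply(expected_list, paste, character(1), collapse = " "))
  expect_identical(got, want)
}
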