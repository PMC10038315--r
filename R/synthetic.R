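#' Random rooted species tree
#'
#' Seeded generator of random S-trees by recursive splitting of the species
#' set: a shuffled label vector is cut into two (or, with probability
#' `multifurcation_prob` when `binary = FALSE`, more) nonempty blocks, each
#' recursively grown into a child subtree. Identical seeds give identical
#' topologies.
#'
#' @param species Character vector of leaf labels (at least one).
#' @param seed Optional integer seed.
#' @param binary Force outdegree exactly 2 everywhere (an evolutionary
#'   tree)?
#' @param multifurcation_prob Probability that a node with three or more
#'   descendant species becomes a multifurcation (ignored when
#'   `binary = TRUE`).
#' @return An `stree`.
#' @export
random_stree <- function(species, seed = NULL, binary = TRUE,
                         multifurcation_prob = 0.25) {
  if (length(species) < 1L) {
    phgt_stop("need at least one species", "domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  split_node <- function(labs) {
    n <- length(labs)
    if (n == 1L) return(leaf_node(labs))
    k <- 2L
    if (!binary && n >= 3L && stats::runif(1) < multifurcation_prob) {
      ks <- seq.int(3L, min(n, 4L))
      k <- ks[sample.int(length(ks), 1L)]
    }
    labs <- sample(labs)
    cuts <- sort(sample(seq_len(n - 1L), k - 1L))
    blocks <- split(labs, findInterval(seq_len(n) - 1L, cuts))
    internal_node(lapply(blocks, split_node))
  }
  new_stree(split_node(as.character(species)))
}

#' Inject a horizontal transfer by leaf regrafting
#'
#' Emulates the tree-level footprint of a horizontal transfer between
#' species `a` and `b`: leaf `b` is detached (collapsing any outdegree-1
#' remnant) and reattached as the sibling of leaf `a`. Whenever a quartet
#' witness exists (at least four species and `a`, `b` not already in a
#' cherry), the resulting tree contradicts the input tree.
#'
#' @param t An `stree`.
#' @param a,b Distinct leaf labels: the transfer partners.
#' @param seed Unused placeholder for interface symmetry with the other
#'   generators (the operation is deterministic).
#' @return The regrafted `stree`.
#' @export
inject_hgt <- function(t, a, b, seed = NULL) {
  stopifnot(inherits(t, "stree"))
  if (identical(a, b)) {
    phgt_stop("transfer partners must be distinct", "domain_error")
  }
  if (!all(c(a, b) %in% t$species)) {
    phgt_stop("transfer partners must be leaves of the tree", "lookup_error")
  }
  if (length(t$species) < 4L) {
    warning("fewer than 4 species: no quartet witness possible, ",
            "tree returned unchanged")
    return(t)
  }
  detach <- function(node) {
    if (is_leaf_node(node)) return(node)
    kids <- Filter(function(k) !(is_leaf_node(k) && k$label == b),
                   node$children)
    kids <- lapply(kids, detach)
    if (length(kids) == 1L) return(kids[[1L]])
    internal_node(kids)
  }
  regraft <- function(node) {
    if (is_leaf_node(node)) {
      if (node$label == a) {
        return(internal_node(list(node, leaf_node(b))))
      }
      return(node)
    }
    internal_node(lapply(node$children, regraft))
  }
  new_stree(regraft(detach(t$root)), t$species)
}

#' Simulated multi-gene poset dataset with known transfers
#'
#' Draws one base species tree, gives every clean gene the poset family
#' generated from it, and gives each listed transfer gene the family of the
#' base tree with that transfer injected by [inject_hgt()]. The ground truth
#' (base tree and injected pairs) is returned alongside, so detection can be
#' scored exactly. Fully reproducible by seed.
#'
#' @param n_species,n_genes Problem size; species are `s1..sn`, genes
#'   `g1..gm`.
#' @param hgt_genes List of transfers, each `list(gene =, a =, b =)` (gene by
#'   label or index).
#' @param seed Integer seed for the base tree draw.
#' @param binary Passed to [random_stree()].
#' @return A list with `families` (named list of [poset_family()]) and
#'   `truth` (`base_tree`, and `injected`: named list gene -> c(a, b)).
#' @export
make_dataset <- function(n_species, n_genes, hgt_genes = list(), seed = 1L,
                         binary = TRUE) {
  species <- paste0("s", seq_len(n_species))
  genes <- paste0("g", seq_len(n_genes))
  base <- random_stree(species, seed = seed, binary = binary)
  injected <- list()
  for (h in hgt_genes) {
    gene <- if (is.numeric(h$gene)) {
      if (h$gene < 1 || h$gene > n_genes) {
        phgt_stop("gene index out of range", "domain_error")
      }
      genes[h$gene]
    } else h$gene
    if (!gene %in% genes) {
      phgt_stop(paste0("unknown gene '", gene, "'"), "domain_error")
    }
    injected[[gene]] <- c(h$a, h$b)
  }
  families <- stats::setNames(lapply(genes, function(g) {
    src <- if (g %in% names(injected)) {
      inject_hgt(base, injected[[g]][1L], injected[[g]][2L])
    } else base
    generate_posets(src, gene = g)
  }), genes)
  list(families = families,
       truth = list(base_tree = base, injected = injected, seed = seed))
}

#' Corrupt a poset family
#'
#' Emulates missing or incorrect input data. `drop` removes each non-focal
#' pair with probability `rate` (the focal-minimum pairs are retained, as the
#' definition of a focal poset forces them); `flip` reverses each non-focal
#' pair with probability `rate` where the reverse is not already present. The
#' output may be invalid or mutually inconsistent by design -- that is the
#' point: downstream tree construction is expected to fail on it.
#'
#' @param fam A [poset_family()].
#' @param mode `"drop"` or `"flip"`.
#' @param rate Per-pair corruption probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return A `poset_family` (possibly invalid).
#' @export
corrupt_posets <- function(fam, mode = c("drop", "flip"), rate, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  posets <- lapply(fam$posets, function(p) {
    m <- p$pairs
    cand <- which(m[, 1L] != p$focal)
    hit <- cand[stats::runif(length(cand)) < rate]
    if (mode == "drop") {
      if (length(hit) > 0L) m <- m[-hit, , drop = FALSE]
    } else {
      for (r in hit) {
        if (!has_pair(m, m[r, 2L], m[r, 1L])) {
          m[r, ] <- m[r, c(2L, 1L)]
        }
      }
    }
    new_poset(p$focal, m, p$species)
  })
  poset_family(fam$gene, posets, fam$species)
}

#' Rank-based posets from a similarity-score matrix
#'
#' Derives a poset family from pairwise similarity scores (e.g. alignment
#' bit scores): for each focal species, a strictly greater score means
#' strictly closer, so the pair (closer, farther) is added; equal scores
#' leave the two species incomparable (the same closeness level). The
#' diagonal is ignored.
#'
#' @param scores Square nonnegative numeric matrix with identical row and
#'   column species labels.
#' @param gene Gene label for the returned family.
#' @return A [poset_family()].
#' @export
posets_from_scores <- function(scores, gene = "g1") {
  if (!is.matrix(scores) || nrow(scores) != ncol(scores) ||
      is.null(rownames(scores)) || is.null(colnames(scores)) ||
      !identical(rownames(scores), colnames(scores))) {
    phgt_stop("scores must be a square labelled matrix", "domain_error")
  }
  if (any(scores < 0)) {
    phgt_stop("scores must be nonnegative", "domain_error")
  }
  species <- rownames(scores)
  posets <- lapply(species, function(focal) {
    others <- setdiff(species, focal)
    sc <- scores[focal, others]
    idx <- which(outer(sc, sc, `>`), arr.ind = TRUE)
    pairs <- rbind(cbind(focal, others),
                   cbind(others[idx[, 1L]], others[idx[, 2L]]))
    new_poset(focal, pairs, species)
  })
  poset_family(gene, posets, species)
}
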