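#' Cluster gene trees by pairwise contradiction
#'
#' Sequential assignment: each tree is compared against the representative
#' (the first member) of every existing cluster, in creation order, and joins
#' the first cluster whose representative it does not contradict; otherwise
#' it founds a new cluster. With `strict = TRUE` a tree must be
#' non-contradictory with every member of a cluster to join it (contradiction
#' is not transitive, so the two modes can differ).
#'
#' @param trees Named list of `stree` objects (names are gene labels), all
#'   over one leaf set.
#' @param strict Compare against all members rather than the representative
#'   only?
#' @return A list of clusters, each `list(genes =, representative =)`.
#' @export
cluster_trees <- function(trees, strict = FALSE) {
  stopifnot(is.list(trees), length(trees) > 0L, !is.null(names(trees)))
  species <- trees[[1L]]$species
  clusters <- list()
  members <- list()  # parallel list of member trees per cluster
  for (gene in names(trees)) {
    t <- trees[[gene]]
    if (!setequal(t$species, species)) {
      phgt_stop(sprintf("gene '%s' tree has a different leaf set", gene),
                "domain_error")
    }
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      against <- if (strict) members[[ci]] else members[[ci]][1L]
      ok <- !any(vapply(against,
                        function(m) isTRUE(as.logical(trees_contradict(m, t))),
                        logical(1)))
      if (ok) {
        clusters[[ci]]$genes <- c(clusters[[ci]]$genes, gene)
        members[[ci]] <- c(members[[ci]], list(t))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- list(genes = gene,
                                                representative = t)
      members[[length(members) + 1L]] <- list(t)
    }
  }
  clusters
}

#' Witness species pairs for a candidate transfer
#'
#' For each contradicting 2-partition pair between a candidate gene tree and
#' the majority tree, reports the two unordered species pairs that the
#' candidate tree unites but the majority tree separates, annotated with both
#' transfer directions per pair (the method cannot resolve donor versus
#' recipient). Non-contradictory inputs yield an empty list.
#'
#' @param candidate,majority `stree` objects over the same leaf set.
#' @return A list of witnesses, each
#'   `list(partition_candidate, partition_majority, pairs, arcs)` where
#'   `pairs` is a list of two character pairs and `arcs` the four possible
#'   donor-to-recipient arcs.
#' @export
witness_transfers <- function(candidate, majority) {
  verdict <- trees_contradict(candidate, majority, all_witnesses = TRUE)
  out <- list()
  seen <- character(0)
  for (w in attr(verdict, "witnesses")) {
    c1 <- w$p1; m1 <- w$p2
    a <- intersect(c1[[1L]], m1[[1L]])[1L]
    b <- intersect(c1[[1L]], m1[[2L]])[1L]
    cc <- intersect(c1[[2L]], m1[[1L]])[1L]
    d <- intersect(c1[[2L]], m1[[2L]])[1L]
    pairs <- list(sort(c(a, b)), sort(c(cc, d)))
    key <- paste(vapply(pairs, paste, character(1), collapse = ","),
                 collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    arcs <- c(paste0(a, "->", b), paste0(b, "->", a),
              paste0(cc, "->", d), paste0(d, "->", cc))
    out[[length(out) + 1L]] <- list(partition_candidate = c1,
                                    partition_majority = m1,
                                    pairs = pairs, arcs = arcs)
  }
  out
}

#' Infer horizontal gene transfer from per-gene poset families
#'
#' The full pipeline: one tree is reconstructed per gene with
#' [construct_tree()] (genes whose posets admit no tree are reported as
#' unconstructible and excluded), the trees are clustered by pairwise
#' contradiction, the largest cluster is declared the majority topology, and
#' every gene outside it is flagged as a horizontal-transfer candidate with
#' witness species pairs against the majority representative. A tie for the
#' largest cluster yields an explicit no-call with all clusters flagged
#' ambiguous. Gene duplication, gene loss, and incomplete lineage sorting can
#' also make gene trees disagree; the report notes these confounders, which
#' the method does not model.
#'
#' @param families Named list of [poset_family()] objects, or a single one.
#' @param strict Passed to [cluster_trees()].
#' @return An object of class `hgt_report`.
#' @export
infer_hgt <- function(families, strict = FALSE) {
  if (inherits(families, "poset_family")) families <- list(families)
  if (is.null(names(families)) || any(!nzchar(names(families)))) {
    names(families) <- vapply(families, function(f) f$gene, character(1))
  }
  trees <- list()
  unconstructible <- list()
  for (gene in names(families)) {
    t <- tryCatch(construct_tree(families[[gene]]),
                  posethgt_error = function(e) e)
    if (inherits(t, "stree")) {
      trees[[gene]] <- t
    } else {
      unconstructible[[gene]] <- conditionMessage(t)
    }
  }
  if (length(trees) == 0L) {
    phgt_stop("no gene admitted a tree", "domain_error")
  }
  clusters <- cluster_trees(trees, strict = strict)
  sizes <- vapply(clusters, function(cl) length(cl$genes), integer(1))
  top <- which(sizes == max(sizes))
  tie <- length(top) > 1L
  majority <- if (tie) NA_integer_ else top[1L]
  candidates <- list()
  if (!tie) {
    rep_tree <- clusters[[majority]]$representative
    for (ci in setdiff(seq_along(clusters), majority)) {
      for (gene in clusters[[ci]]$genes) {
        candidates[[length(candidates) + 1L]] <- list(
          gene = gene,
          cluster = ci,
          witnesses = witness_transfers(trees[[gene]], rep_tree))
      }
    }
  }
  structure(list(clusters = clusters,
                 majority = majority,
                 tie = tie,
                 candidates = candidates,
                 unconstructible = unconstructible,
                 trees = trees,
                 confounders = paste(
                   "gene duplication, gene loss, and incomplete lineage",
                   "sorting can also cause gene-tree incongruence and are",
                   "not modelled")),
            class = "hgt_report")
}

#' @export
print.hgt_report <- function(x, ...) {
  cat("HGT inference report\n")
  cat(sprintf("  genes analysed: %d (plus %d unconstructible)\n",
              length(x$trees), length(x$unconstructible)))
  cat(sprintf("  clusters: %d\n", length(x$clusters)))
  if (x$tie) {
    cat("  majority: no call (tie between largest clusters)\n")
  } else {
    cat(sprintf("  majority cluster: #%d (%d gene(s)); representative %s\n",
                x$majority, length(x$clusters[[x$majority]]$genes),
                write_newick(x$clusters[[x$majority]]$representative)))
    if (length(x$candidates) == 0L) {
      cat("  no HGT candidates\n")
    } else {
      for (cand in x$candidates) {
        prs <- unique(unlist(lapply(cand$witnesses, function(w)
          vapply(w$pairs, paste, character(1), collapse = "<->"))))
        cat(sprintf("  candidate gene %s: possible transfer between %s\n",
                    cand$gene, paste(prs, collapse = " or ")))
      }
    }
  }
  invisible(x)
}

#' @export
summary.hgt_report <- function(object, ...) {
  data.frame(
    gene = names(object$trees),
    cluster = vapply(names(object$trees), function(g) {
      which(vapply(object$clusters, function(cl) g %in% cl$genes,
                   logical(1)))[1L]
    }, integer(1)),
    candidate = names(object$trees) %in%
      vapply(object$candidates, function(cd) cd$gene, character(1)),
    row.names = NULL)
}

# JSON-ready form of a report (used by the CLI).
hgt_report_to_list <- function(x) {
  list(
    clusters = lapply(x$clusters, function(cl) list(
      genes = as.list(cl$genes),
      representative_newick = write_newick(cl$representative))),
    majority = if (x$tie) NULL else x$majority,
    tie = x$tie,
    confounders = x$confounders,
    unconstructible = x$unconstructible,
    candidates = lapply(x$candidates, function(cd) list(
      gene = cd$gene,
      witnesses = lapply(cd$witnesses, function(w) list(
        partition_a = lapply(unclass(w$partition_candidate), as.list),
        partition_b = lapply(unclass(w$partition_majority), as.list),
        pairs = lapply(w$pairs, as.list),
        arcs = as.list(w$arcs))))))
}
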