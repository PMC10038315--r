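#' Species-anchored partial orders
#'
#' A species-anchored poset records, for one focal species, the relative
#' closeness of all other species to it: the strict pair (a, b) means that
#' species `a` is strictly closer to the focal species than `b` is. The focal
#' species is the unique minimum of the order, so the pairs (focal, x) for
#' every other species x are always present; they are auto-completed (with a
#' notice) when missing from the input. Input pairs may be cover relations
#' (Hasse-diagram edges) or the full relation -- the transitive closure is
#' always computed, so the two encodings are equivalent.
#'
#' @param focal Focal species label (character scalar).
#' @param pairs Strict order pairs: a 2-column matrix, data frame, or list of
#'   length-2 character vectors, each `(lesser, greater)`.
#' @param species Character vector of all species labels (the ground set).
#'   Species mentioned in no pair are incomparable to everything except the
#'   focal species.
#' @return An object of class `poset`: a list with elements `focal`, `pairs`
#'   (2-column character matrix, transitively closed, reflexive pairs never
#'   stored), and `species`.
#' @examples
#' p <- poset("s1", list(c("s1", "s2"), c("s2", "s3")), c("s1", "s2", "s3"))
#' p$pairs
#' @export
poset <- function(focal, pairs = NULL, species) {
  stopifnot(is.character(focal), length(focal) == 1L, is.character(species))
  species <- unique(species)
  if (!focal %in% species) {
    phgt_stop(sprintf("focal species '%s' not in species set", focal),
              "domain_error")
  }
  m <- as_pair_matrix(pairs)
  bad <- setdiff(unique(c(m)), species)
  if (length(bad) > 0L) {
    phgt_stop(paste0("unknown species label(s) in pairs: ",
                     paste(bad, collapse = ", ")), "domain_error")
  }
  m <- m[m[, 1L] != m[, 2L], , drop = FALSE]  # drop reflexive input
  m <- transitive_closure(m)
  missing_min <- setdiff(species, c(focal, m[m[, 1L] == focal, 2L]))
  if (length(missing_min) > 0L) {
    phgt_note("auto-completing ", length(missing_min),
              " focal-minimum pair(s) for ", focal)
    m <- as_pair_matrix(rbind(m, cbind(focal, missing_min)))
    m <- transitive_closure(m)
  }
  new_poset(focal, m, species)
}

# Internal constructor: no closure, no completion. Used where invalid posets
# are wanted on purpose (corruption) or validity is guaranteed (generation).
new_poset <- function(focal, pairs, species) {
  structure(list(focal = focal, pairs = as_pair_matrix(pairs),
                 species = species),
            class = "poset")
}

#' @export
print.poset <- function(x, ...) {
  cat(sprintf("%s-poset on %d species, %d strict pair(s)\n",
              x$focal, length(x$species), nrow(x$pairs)))
  if (nrow(x$pairs) > 0L) {
    cat(paste0("  ", x$pairs[, 1L], " < ", x$pairs[, 2L]), sep = "\n")
  }
  invisible(x)
}

#' Transitive closure of a strict order
#'
#' Computes the smallest transitively closed superset of a set of strict
#' pairs, by Warshall's algorithm on the labels that occur. The operation is
#' idempotent and monotone. If the closure would ever contain both (a, b) and
#' (b, a), the input encodes a cycle and an antisymmetry error naming the
#' cycle members is raised.
#'
#' @param pairs Strict pairs in any form accepted by [poset()].
#' @return A 2-column character matrix of the closed relation.
#' @examples
#' transitive_closure(list(c("a", "b"), c("b", "c")))
#' @export
transitive_closure <- function(pairs) {
  m <- as_pair_matrix(pairs)
  if (nrow(m) == 0L) return(m)
  labs <- sort(unique(c(m)))
  n <- length(labs)
  rel <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  rel[m] <- TRUE
  for (k in seq_len(n)) {
    rel <- rel | outer(rel[, k], rel[k, ], `&`)
  }
  cyc <- which(rel & t(rel), arr.ind = TRUE)
  if (nrow(cyc) > 0L) {
    members <- sort(unique(labs[c(cyc)]))
    phgt_stop(paste0("antisymmetry violated: cycle among {",
                     paste(members, collapse = ", "), "}"),
              "antisymmetry_violation", cycle = members)
  }
  diag(rel) <- FALSE
  idx <- which(rel, arr.ind = TRUE)
  as_pair_matrix(cbind(labs[idx[, 1L]], labs[idx[, 2L]]))
}

#' Validate a species-anchored poset
#'
#' Checks the four structural invariants: transitive closure, antisymmetry
#' (with irreflexivity), the focal species being the unique minimum, and all
#' labels being drawn from the declared species set.
#'
#' @param p A [poset()] (possibly hand-built and broken).
#' @return A list with `valid` (logical) and `errors` (character vector
#'   naming each violated invariant and the offending pairs).
#' @export
validate_poset <- function(p) {
  errors <- character(0)
  m <- p$pairs
  bad_lab <- setdiff(unique(c(m)), p$species)
  if (length(bad_lab) > 0L) {
    errors <- c(errors, paste0("unknown labels: ",
                               paste(bad_lab, collapse = ", ")))
  }
  refl <- m[, 1L] == m[, 2L]
  if (any(refl)) {
    errors <- c(errors, paste0("reflexive pairs stored: ",
                               paste(m[refl, 1L], collapse = ", ")))
  }
  keys <- pair_keys(m)
  rev_keys <- pair_keys(m[, c(2L, 1L), drop = FALSE])
  sym <- rev_keys %in% keys & !refl
  if (any(sym)) {
    offender <- m[which(sym)[1L], ]
    errors <- c(errors, sprintf("antisymmetry violated: both (%s,%s) and (%s,%s)",
                                offender[1L], offender[2L],
                                offender[2L], offender[1L]))
  }
  if (nrow(m) > 1L) {
    joins <- merge(data.frame(a = m[, 1L], b = m[, 2L]),
                   data.frame(b = m[, 1L], c = m[, 2L]))
    if (nrow(joins) > 0L) {
      need <- paste(joins$a, joins$c, sep = "\r")
      miss <- !(need %in% keys) & joins$a != joins$c
      if (any(miss)) {
        j <- joins[which(miss)[1L], ]
        errors <- c(errors, sprintf(
          "not transitively closed: (%s,%s) and (%s,%s) but no (%s,%s)",
          j$a, j$b, j$b, j$c, j$a, j$c))
      }
    }
  }
  below <- setdiff(p$species, c(p$focal, m[m[, 1L] == p$focal, 2L]))
  if (length(below) > 0L) {
    errors <- c(errors, paste0("focal minimum missing for: ",
                               paste(below, collapse = ", ")))
  }
  if (any(m[, 2L] == p$focal)) {
    errors <- c(errors, "focal species is above another species")
  }
  list(valid = length(errors) == 0L, errors = errors)
}

#' Per-gene family of posets
#'
#' Bundles one poset per species, all over the same species set, for a single
#' gene. This is the unit from which a gene tree is reconstructed.
#'
#' @param gene Gene label.
#' @param posets A list of [poset()] objects, one per species (named by focal
#'   species or in any order -- focal labels are used).
#' @param species Optional species set; defaults to the first poset's.
#' @return An object of class `poset_family` with elements `gene`, `posets`
#'   (named list, one per species), and `species`.
#' @export
poset_family <- function(gene, posets, species = NULL) {
  stopifnot(is.list(posets), length(posets) > 0L)
  focals <- vapply(posets, function(p) p$focal, character(1))
  names(posets) <- focals
  species <- species %||% posets[[1L]]$species
  if (anyDuplicated(focals)) {
    phgt_stop("duplicate focal species in family", "domain_error")
  }
  same <- vapply(posets, function(p) setequal(p$species, species), logical(1))
  if (!all(same)) {
    phgt_stop("all posets in a family must share one species set",
              "domain_error")
  }
  missing <- setdiff(species, focals)
  if (length(missing) > 0L) {
    phgt_stop(paste0("incomplete family for gene '", gene, "': no poset for ",
                     paste(missing, collapse = ", ")),
              "incomplete_family_error")
  }
  structure(list(gene = gene, posets = posets[order(names(posets))],
                 species = species),
            class = "poset_family")
}

#' @export
print.poset_family <- function(x, ...) {
  cat(sprintf("poset family for gene '%s': %d species (%s)\n",
              x$gene, length(x$species),
              paste(sort(x$species), collapse = ", ")))
  invisible(x)
}

#' Mutual consistency of a poset family
#'
#' A family is consistent when the posets agree with each other about
#' relative closeness: whenever species k is at least as far from the focal
#' species i as j is (j below k in the i-poset), then k must also lie above i
#' in the j-poset. Consistency is what guarantees a symmetric sibling matrix
#' and hence a reconstructible tree.
#'
#' @param fam A [poset_family()].
#' @return A list with `consistent` (logical) and, when inconsistent,
#'   `violation`, the first violating triple `c(i, j, k)` meaning j < k in
#'   the i-poset but i < k absent from the j-poset.
#' @export
is_consistent <- function(fam) {
  if (!inherits(fam, "poset_family")) {
    phgt_stop("expected a poset_family", "domain_error")
  }
  for (p in fam$posets) {
    m <- p$pairs
    strict <- m[m[, 1L] != p$focal, , drop = FALSE]
    for (r in seq_len(nrow(strict))) {
      a <- strict[r, 1L]; b <- strict[r, 2L]
      other <- fam$posets[[a]]
      if (!has_pair(other$pairs, p$focal, b)) {
        return(list(consistent = FALSE,
                    violation = unname(c(p$focal, a, b))))
      }
    }
  }
  list(consistent = TRUE, violation = NULL)
}
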