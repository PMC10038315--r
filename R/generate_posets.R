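#' Generate the compatible poset family from a tree
#'
#' For each leaf, the walk from that leaf to the root yields a sequence of
#' nested subtrees; the species newly contributed by each successive subtree
#' form closeness levels 1, 2, ... around the focal species (level 0). The
#' focal poset contains exactly the pairs (a, b) with level(a) < level(b):
#' species within a level are incomparable. The resulting family is mutually
#' consistent, and every poset in it is compatible with the source tree.
#'
#' @param t An `stree`.
#' @param gene Gene label attached to the returned family.
#' @return A [poset_family()] with one poset per species.
#' @examples
#' fam <- generate_posets(parse_newick("(((s1,s2),s3),(s4,s5));"))
#' fam$posets$s1$pairs
#' @export
generate_posets <- function(t, gene = "g1") {
  stopifnot(inherits(t, "stree"))
  posets <- lapply(sort(t$species), function(focal) {
    lv <- focal_levels(t, focal)
    labs <- names(lv)
    idx <- which(outer(lv, lv, `<`), arr.ind = TRUE)
    pairs <- cbind(labs[idx[, 1L]], labs[idx[, 2L]])
    new_poset(focal, pairs, t$species)
  })
  poset_family(gene, posets, t$species)
}
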