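Package: posetHGT
Title: Inferring Horizontal Gene Transfer from Partial Orders of Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate horizontally transferred genes from families of
    species-anchored partial orders (posets). For each gene, a rooted species
    tree is reconstructed from the per-species posets via a sibling-count
    matrix; conversely, the compatible poset family can be generated from any
    rooted tree. Gene trees are compared through the 2-partitions induced by
    their edges: trees whose partitions cross on a quadruple of species are
    contradictory, non-contradictory trees admit a minimum common refinement,
    and genes whose trees contradict the majority topology are flagged as
    horizontal gene transfer candidates together with witness species pairs.
    Includes seeded simulators for random rooted trees, transfer injection by
    leaf regrafting, poset corruption, and rank-derived posets from
    similarity scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
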