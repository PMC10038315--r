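tbl <- function(values, labs) {
  m <- matrix(values, length(labs), length(labs), byrow = TRUE,
              dimnames = list(labs, labs))
  storage.mode(m) <- "integer"
  posetHGT:::new_sibling_matrix(m, stats::setNames(as.list(labs), labs))
}

test_that("the sibling matrix reproduces the printed four-species table", {
  a <- build_matrix(paper_family_4sp())
  expect_identical(unname(unclass(a)[, ]),
                   matrix(c(-1L, 1L, 1L, 0L,
                            1L, -1L, 1L, 0L,
                            1L, 1L, -1L, 0L,
                            0L, 0L, 0L, -1L), 4, byrow = TRUE))
  expect_true(validate_matrix(a))
})

test_that("the five-taxon matrix and its reduction chain are exact", {
  fam <- generate_posets(fig12_tree())
  a <- build_matrix(fam)
  labs5 <- paste0("s", 1:5)
  expect_identical(unclass(a)[, ],
                   matrix(c(-1L, 3L, 2L, 0L, 0L,
                            3L, -1L, 2L, 0L, 0L,
                            2L, 2L, -1L, 0L, 0L,
                            0L, 0L, 0L, -1L, 3L,
                            0L, 0L, 0L, 3L, -1L), 5, byrow = TRUE,
                          dimnames = list(labs5, labs5)))
  expect_identical(find_max(a), 3L)
  groups <- find_sibling_groups(a)
  expect_identical(groups, list(c("s1", "s2"), c("s4", "s5")))

  forest <- stats::setNames(lapply(labs5, posetHGT:::leaf_node), labs5)
  step1 <- merge_siblings(a, c("s1", "s2"), forest)
  expect_identical(unname(unclass(step1$matrix)["<s1,s2>", ]),
                   c(2L, 0L, 0L, -1L))
  expect_identical(unname(unclass(step1$matrix)[, "s3"])[1:3],
                   c(-1L, 0L, 0L))
  step2 <- merge_siblings(step1$matrix, c("s4", "s5"), step1$forest)
  m4 <- unclass(step2$matrix)
  expect_identical(dim(m4), c(3L, 3L))
  expect_identical(find_max(step2$matrix), 2L)
  step3 <- merge_siblings(step2$matrix,
                          find_sibling_groups(step2$matrix)[[1L]],
                          step2$forest)
  expect_identical(find_max(step3$matrix), 0L)
})

test_that("asymmetric matrices are flagged invalid", {
  m <- tbl(c(-1, 3, 2, -1), c("s1", "s2"))
  m[1, 2] <- 3L; m[2, 1] <- 2L
  expect_false(validate_matrix(m))
  expect_true(validate_matrix(tbl(-1, "s1")))
  expect_error(find_max(tbl(-1, "s1")), class = "degenerate_input_error")
})

test_that("six-taxon triple cherries give two sibling triples", {
  fam <- generate_posets(parse_newick("((s1,s2,s3),(s4,s5,s6));"))
  a <- build_matrix(fam)
  expect_identical(find_max(a), 3L)
  expect_identical(find_sibling_groups(a),
                   list(c("s1", "s2", "s3"), c("s4", "s5", "s6")))
})

test_that("the star rule groups a hub with both cliques' parents", {
  labs <- c("s1", "s2", "s3", "s4", "s5")
  a <- tbl(c(-1, 3, 0, 0, 2,
             3, -1, 0, 0, 2,
             0, 0, -1, 3, 2,
             0, 0, 3, -1, 2,
             2, 2, 2, 2, -1), labs)
  expect_identical(find_max(a), 3L)
  expect_identical(find_sibling_groups(a),
                   list(c("s1", "s2"), c("s3", "s4")))
  forest <- stats::setNames(lapply(labs, posetHGT:::leaf_node), labs)
  r <- merge_siblings(a, c("s1", "s2"), forest)
  r <- merge_siblings(r$matrix, c("s3", "s4"), r$forest)
  m <- unclass(r$matrix)
  expect_identical(unname(m["s5", ]), c(-1L, 2L, 2L))
  expect_identical(unname(m["<s1,s2>", "<s3,s4>"]), 0L)
  # max 2 edges form a star through s5: one parent for all three
  expect_message(
    g <- find_sibling_groups(r$matrix),
    "non-clique")
  expect_identical(g, list(c("<s1,s2>", "<s3,s4>", "s5")))
  r2 <- merge_siblings(r$matrix, g[[1L]], r$forest)
  expect_identical(dim(unclass(r2$matrix)), c(1L, 1L))
  t <- posetHGT:::new_stree(r2$forest[[1L]])
  expect_identical(write_newick(t), "((s1,s2),(s3,s4),s5);")
})

test_that("merge conflicts surface as inconsistency errors", {
  a <- tbl(c(-1, 3, 2,
             3, -1, 1,
             2, 1, -1), c("s1", "s2", "s3"))
  forest <- stats::setNames(lapply(c("s1", "s2", "s3"),
                                   posetHGT:::leaf_node),
                            c("s1", "s2", "s3"))
  expect_error(merge_siblings(a, c("s1", "s2"), forest),
               class = "inconsistency_error")
})

test_that("construct_tree recovers the printed example trees", {
  expect_identical(write_newick(construct_tree(generate_posets(fig12_tree()))),
                   "(((s1,s2),s3),(s4,s5));")
  expect_identical(
    write_newick(construct_tree(generate_posets(
      parse_newick("((s1,s2,s3),(s4,s5,s6));")))),
    "((s1,s2,s3),(s4,s5,s6));")
  expect_identical(write_newick(construct_tree(paper_family_4sp())),
                   "((s1,s2,s3),s4);")
  # single species
  solo <- poset_family("g", list(poset("s1", NULL, "s1")))
  expect_identical(write_newick(construct_tree(solo)), "s1;")
})

test_that("construct_tree rejects inconsistent families", {
  S <- c("s1", "s2", "s3")
  P1 <- poset("s1", list(c("s1", "s2"), c("s1", "s3"), c("s2", "s3")), S)
  P2 <- poset("s2", list(c("s2", "s1"), c("s2", "s3"), c("s1", "s3")), S)
  P4 <- poset("s3", list(c("s3", "s1"), c("s3", "s2"), c("s1", "s2")), S)
  fam <- poset_family("g", list(P1, P2, P4))
  expect_false(is_consistent(fam)$consistent)
  expect_error(construct_tree(fam), class = "inconsistency_error")
})

test_that("construction inverts generation on random trees", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    t <- random_stree(paste0("s", seq_len(n)),
                      binary = sample(c(TRUE, FALSE), 1),
                      multifurcation_prob = 0.4)
    fam <- generate_posets(t)
    a <- build_matrix(fam)
    expect_true(validate_matrix(a))
    expect_true(stree_equal(construct_tree(fam), t))
  }
})
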