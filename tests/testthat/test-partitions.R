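test_that("edge cuts give the printed partition lists", {
  # root children (s1,s2,s3) and (s4,s5), plus the s0 augmentation
  t1 <- parse_newick("((s1,s2,s3),(s4,s5));")
  q1 <- find_two_partitions(t1, augment = TRUE)
  expect_length(q1, 8L)
  keys <- partition_keyset(q1)
  expect_true("s0,s4,s5|s1,s2,s3" %in% keys)
  expect_true("s4,s5|s0,s1,s2,s3" %in% keys)
  expect_true("s0|s1,s2,s3,s4,s5" %in% keys)
  expect_length(grep("^s[0-9]\\|", keys), 6L)  # six singleton cuts

  t2 <- parse_newick("(((s1,s2),s3),s4,s5);")
  q2 <- find_two_partitions(t2, augment = TRUE)
  expect_length(q2, 8L)
  keys2 <- partition_keyset(q2)
  expect_true("s1,s2|s0,s3,s4,s5" %in% keys2)
  expect_true("s0,s4,s5|s1,s2,s3" %in% keys2)

  union_keys <- sort(unique(c(keys, keys2)))
  expect_length(union_keys, 9L)

  # both edges of a 2-leaf tree induce the same, deduplicated partition
  expect_length(find_two_partitions(parse_newick("(s1,s2);")), 1L)
  # star tree on 3 leaves + s0: four singleton-vs-rest cuts
  q <- find_two_partitions(parse_newick("(s1,s2,s3);"), augment = TRUE)
  expect_length(q, 4L)
  expect_true(all(lengths(lapply(q, `[[`, 1L)) == 1L))
})

test_that("the s0 label must be free for augmentation", {
  expect_error(
    find_two_partitions(parse_newick("(s0,s1);"), augment = TRUE),
    class = "label_collision_error")
})

test_that("partition contradiction follows the crossing-quadruple rule", {
  x <- two_partition(c("s1", "s2"), c("s3", "s4"))
  y <- two_partition(c("s1", "s3"), c("s2", "s4"))
  expect_true(partitions_contradict(x, y))
  expect_false(partitions_contradict(x, x))
  z <- two_partition("s1", c("s2", "s3", "s4"))
  expect_false(partitions_contradict(z, x))
  expect_false(partitions_contradict(z, y))
  expect_error(
    partitions_contradict(x, two_partition("a", c("b", "c", "d"))),
    class = "domain_error")
})

test_that("intersection test agrees with exhaustive quadruple search", {
  set.seed(61)
  for (n in 4:8) {
    sp <- paste0("s", seq_len(n))
    for (rep in 1:12) {
      cut1 <- sample(n - 1, 1)
      cut2 <- sample(n - 1, 1)
      s1 <- sample(sp, cut1)
      x <- two_partition(s1, setdiff(sp, s1))
      s2 <- sample(sp, cut2)
      y <- two_partition(s2, setdiff(sp, s2))
      expect_identical(partitions_contradict(x, y),
                       oracle_partitions_contradict(x, y))
    }
  }
})

test_that("a tree's own partition set never contradicts itself", {
  set.seed(67)
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    t <- random_stree(paste0("s", seq_len(n)), binary = FALSE,
                      multifurcation_prob = 0.5)
    q <- find_two_partitions(t, augment = TRUE)
    for (i in seq_along(q)) {
      for (j in seq_len(i - 1L)) {
        expect_false(partitions_contradict(q[[i]], q[[j]]))
      }
    }
  }
})

test_that("tree contradiction matches the cherry-swap example", {
  c1 <- parse_newick("(((s1,s2),s3),s4);")
  c2 <- parse_newick("(((s1,s3),s2),s4);")
  v <- trees_contradict(c1, c2)
  expect_true(as.logical(v))
  w <- attr(v, "witnesses")[[1L]]
  expect_true(partitions_contradict(w$p1, w$p2))
  expect_false(as.logical(trees_contradict(c1, c1)))
  expect_error(trees_contradict(c1, parse_newick("(s1,s2);")),
               class = "domain_error")
})

test_that("refinements never contradict their base tree", {
  set.seed(71)
  for (rep in 1:30) {
    n <- sample(4:10, 1)
    t <- random_stree(paste0("s", seq_len(n)), binary = FALSE,
                      multifurcation_prob = 0.6)
    base <- contract_tree(t, prob = 0.7)
    # t refines base... only when contraction was built from t itself
    expect_false(as.logical(trees_contradict(base, t)))
    qb <- partition_keyset(find_two_partitions(base, augment = TRUE))
    qt <- partition_keyset(find_two_partitions(t, augment = TRUE))
    expect_true(all(qb %in% qt))
  }
})

test_that("trees rebuild exactly from their augmented partition sets", {
  # the nine-partition worked example
  q <- c(find_two_partitions(parse_newick("((s1,s2,s3),(s4,s5));"),
                             augment = TRUE),
         find_two_partitions(parse_newick("(((s1,s2),s3),s4,s5);"),
                             augment = TRUE))
  q <- q[!duplicated(vapply(q, posetHGT:::partition_key, character(1)))]
  expect_identical(write_newick(construct_tree_from_partitions(q)),
                   "(((s1,s2),s3),(s4,s5));")

  # star tree: only singleton partitions survive, root adopts all leaves
  qs <- find_two_partitions(parse_newick("(s1,s2,s3);"), augment = TRUE)
  expect_identical(write_newick(construct_tree_from_partitions(qs)),
                   "(s1,s2,s3);")

  set.seed(73)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    t <- random_stree(paste0("s", seq_len(n)), binary = FALSE,
                      multifurcation_prob = 0.5)
    rebuilt <- construct_tree_from_partitions(
      find_two_partitions(t, augment = TRUE))
    expect_true(stree_equal(rebuilt, t))
  }
})

test_that("contradictory partition sets are refused", {
  q <- list(two_partition(c("s1", "s2"), c("s0", "s3", "s4")),
            two_partition(c("s1", "s3"), c("s0", "s2", "s4")))
  expect_error(construct_tree_from_partitions(q),
               class = "contradiction_error")
})

test_that("minimum common refinement matches the worked examples", {
  t1 <- parse_newick("((s1,s2),s3,s4);")
  t2 <- parse_newick("((s1,s2),(s3,s4));")
  expect_true(stree_equal(min_common_refinement(t1, t2), t2))

  a <- parse_newick("((s1,s2,s3),(s4,s5));")
  b <- parse_newick("(((s1,s2),s3),s4,s5);")
  r <- min_common_refinement(a, b)
  expect_identical(write_newick(r), "(((s1,s2),s3),(s4,s5));")
  expect_identical(
    partition_keyset(find_two_partitions(r, augment = TRUE)),
    sort(unique(c(
      partition_keyset(find_two_partitions(a, augment = TRUE)),
      partition_keyset(find_two_partitions(b, augment = TRUE))))))

  # idempotence
  t <- fig12_tree()
  expect_true(stree_equal(min_common_refinement(t, t), t))

  expect_error(
    min_common_refinement(parse_newick("(((s1,s2),s3),s4);"),
                          parse_newick("(((s1,s3),s2),s4);")),
    class = "contradiction_error")
})

test_that("partition-set union equality holds for random coarsening pairs", {
  set.seed(79)
  done <- 0L
  while (done < 30L) {
    n <- sample(4:10, 1)
    t <- random_stree(paste0("s", seq_len(n)), binary = FALSE,
                      multifurcation_prob = 0.5)
    t1 <- contract_tree(t, prob = 0.6)
    t2 <- contract_tree(t, prob = 0.6)
    if (as.logical(trees_contradict(t1, t2))) next  # cannot happen; guard
    r <- min_common_refinement(t1, t2)
    expect_identical(
      partition_keyset(find_two_partitions(r, augment = TRUE)),
      sort(unique(c(
        partition_keyset(find_two_partitions(t1, augment = TRUE)),
        partition_keyset(find_two_partitions(t2, augment = TRUE))))))
    # the refinement contains both inputs' partitions
    done <- done + 1L
  }
})
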