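# Tree structures, canonical forms, splits, forgetful maps, enumeration.

test_that("newick parsing and writing round-trip through canonical form", {
  expect_identical(write_newick(parse_newick("(1,2);")), "(1,2);")
  expect_identical(write_newick(parse_newick("(2,1);")), "(1,2);")
  expect_identical(write_newick(parse_newick("((3,4),(1,2));")), "((1,2),(3,4));")
  expect_identical(write_newick(parse_newick("((,),);", mode = "shape")), "(,(,));")
  # the counterexample tree renders with its balanced 4-leaf subtree first
  # (canonical child order: leaf count, then shape encoding, then labels)
  expect_identical(write_newick(t_tilde()), "(((1,2),(3,4)),(8,(7,(5,6))));")
  set.seed(5)
  for (i in 1:25) {
    s <- random_newick(sample(2:9, 1))
    t <- parse_newick(s)
    expect_true(tree_equal(parse_newick(write_newick(t)), t))
  }
  # ordered trees keep their order
  o <- parse_newick("(2,1);", mode = "ordered_cladogram")
  expect_identical(write_newick(o), "(2,1);")
})

test_that("malformed newick is rejected with a position", {
  expect_error(parse_newick("((1,2,3),4);"), "non-binary")
  expect_error(parse_newick("((1,2),(3,1));"), "duplicate")
  expect_error(parse_newick("((1,2);"), "parse error")
  expect_error(parse_newick("((,),);"), "labeled")   # cladogram mode needs labels
  expect_error(parse_newick("(1,2)x;"), "internal node labels")
})

test_that("kappa counts descendant leaves", {
  t <- fig2_tree()
  expect_identical(kappa(t), 7L)
  expect_identical(kappa(t, c(1, 1)), 1L)
  # in canonical order the root's children are the cherry then the 5-leaf part;
  # the 4-leaf node inside the 5-leaf subtree:
  expect_identical(kappa(t, c(2, 2)), 4L)
})

test_that("numerical splits match the worked multisets", {
  expect_equal(unclass(numerical_splits(fig2_tree())),
               matrix(c(1, 1, 1, 1, 1, 1, 1, 4, 2, 2, 2, 5), ncol = 2,
                      byrow = TRUE, dimnames = list(NULL, c("a", "b"))))
  expect_equal(nrow(numerical_splits(parse_newick("(1,2);"))), 1)
  cat4 <- parse_newick(NWK_CAT4)
  expect_equal(unclass(numerical_splits(cat4))[, 1], c(1, 1, 1))
  expect_equal(unclass(numerical_splits(cat4))[, 2], c(1, 2, 3))
  # ordered splits follow the child order; unordered are their sorted pairs
  set.seed(8)
  for (i in 1:20) {
    o <- parse_newick(random_newick(sample(3:8, 1)), mode = "ordered_cladogram")
    so <- unclass(numerical_splits(o))
    su <- unclass(numerical_splits(forget_order(o)))
    sorted <- cbind(pmin(so[, 1], so[, 2]), pmax(so[, 1], so[, 2]))
    expect_equal(su[order(su[, 1], su[, 2]), , drop = FALSE],
                 unname(sorted[order(sorted[, 1], sorted[, 2]), , drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("symmetric branch points are counted through shape isomorphism", {
  expect_identical(symmetric_branch_count(parse_newick("(1,2);")), 1L)
  expect_identical(symmetric_branch_count(t_tilde()), 4L)
  expect_identical(symmetric_branch_count(fig2_tree()), 4L)
  expect_identical(symmetric_branch_count(parse_newick(NWK_CAT4)), 1L)
})

test_that("forgetful maps commute and identify equal shapes", {
  t1 <- parse_newick("(((1,2),3),(4,5));")
  t2 <- parse_newick("(((2,4),5),(1,3));")
  expect_true(tree_equal(shape_of(t1), shape_of(t2)))
  set.seed(13)
  for (i in 1:50) {
    o <- parse_newick(random_newick(8), mode = "ordered_cladogram")
    via_order <- forget_labels(forget_order(o))
    via_labels <- forget_order(forget_labels(o))
    expect_true(tree_equal(via_order, via_labels))
    expect_true(tree_equal(via_order, shape_of(o)))
  }
})

test_that("preimage counts agree with brute-force enumeration", {
  tt_shape <- shape_of(t_tilde())
  expect_equal(preimage_count(tt_shape, "pi"), factorial(8) / 2^4)   # 2520
  expect_equal(preimage_count(tt_shape, "pi_o_star"), 8)
  expect_equal(preimage_count(fig2_tree(), "pi_o"), 64)
  for (n in 3:6) {
    for (s in enumerate_shapes(n)) {
      k <- symmetric_branch_count(s)
      expect_equal(length(all_labelings(s)), factorial(n) / 2^k)
      reps <- all_orderings(label_shape(s))
      oshapes <- unique(vapply(reps, function(o) write_newick(forget_labels(o)),
                               character(1)))
      expect_equal(length(oshapes), 2^(n - 1 - k))
      expect_equal(length(reps), preimage_count(label_shape(s), "pi_o"))
    }
  }
})

test_that("root join concatenates splits and builds the counterexample", {
  cherry <- root_join(parse_newick("1;"), parse_newick("2;"))
  expect_identical(write_newick(cherry), "(1,2);")
  bal4 <- shape_of(parse_newick(NWK_BAL4))
  cat4 <- shape_of(parse_newick(NWK_CAT4))
  expect_true(tree_equal(root_join(bal4, cat4), shape_of(t_tilde())))
  expect_error(root_join(parse_newick("(1,2);"), parse_newick("(2,3);")),
               "disjoint")
  set.seed(2)
  for (i in 1:20) {
    a <- parse_newick(random_newick(4))
    b <- parse_newick(random_newick(4, labels = 4 + sample(4)))
    j <- root_join(a, b)
    sj <- unclass(numerical_splits(j))
    manual <- rbind(unclass(numerical_splits(a)), unclass(numerical_splits(b)),
                    c(4, 4))
    expect_equal(sj[order(sj[, 1], sj[, 2]), , drop = FALSE],
                 manual[order(manual[, 1], manual[, 2]), , drop = FALSE])
  }
})

test_that("enumerations have the right cardinalities and no duplicates", {
  we <- c(1, 1, 1, 2, 3, 6, 11, 23, 46, 98)
  for (n in 1:10) expect_length(enumerate_shapes(n), we[n])
  for (n in 2:6) {
    cl <- enumerate_cladograms(n)
    expect_length(cl, prod(seq(1, 2 * n - 3, by = 2)))
    expect_false(anyDuplicated(vapply(cl, write_newick, character(1))) > 0)
  }
  cat_counts <- c(1, 1, 2, 5, 14, 42, 132, 429)
  for (n in 1:8) expect_length(enumerate_ordered_shapes(n), cat_counts[n])
  expect_error(enumerate_cladograms(9), "1 <= n <= 8")
})

test_that("cladograms partition over shapes by n!/2^k", {
  for (n in 2:8) {
    total <- sum(vapply(enumerate_shapes(n), function(s) {
      factorial(n) / 2^symmetric_branch_count(s)
    }, numeric(1)))
    expect_equal(total, prod(seq(1, 2 * n - 3, by = 2)))
  }
})

test_that("canonical-form isomorphism agrees with the brute-force test", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(2:10, 1)
    s1 <- shape_of(parse_newick(random_newick(n)))
    s2 <- shape_of(parse_newick(random_newick(n)))
    expect_identical(tree_equal(s1, s2), iso_brute(tree_root(s1), tree_root(s2)))
  }
})
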