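# The leaf-addition process: exhaustive histories (the brute-force oracle)
# and the seeded sampler.

test_that("every cladogram arises from exactly one growth history", {
  for (n in 3:5) {
    h <- enumerate_histories(n)
    expect_identical(h$n_histories, as.integer(prod(seq(1, 2 * n - 3, by = 2))))
    expect_false(anyDuplicated(h$cladogram_newick) > 0)
  }
})

test_that("history masses total one and reproduce the closed forms", {
  for (n in 3:6) {
    h <- enumerate_histories(n)
    total <- parse_alpha_fun("0")
    for (mass in h$shape_mass) total <- total + mass
    expect_true(total == parse_alpha_fun("1"))
    for (i in seq_len(nrow(h$shapes))) {
      shp <- parse_newick(h$shapes$newick[i], mode = "shape")
      expect_true(h$shape_mass[[i]] == prob_shape(shp)$fun)
    }
  }
})

test_that("per-cladogram transport: (2^k/n!) x shape mass = cladogram probability", {
  for (n in 3:6) {
    h <- enumerate_histories(n)
    for (i in seq_len(nrow(h$shapes))) {
      shp <- parse_newick(h$shapes$newick[i], mode = "shape")
      k <- symmetric_branch_count(shp)
      lhs <- h$shape_mass[[i]] * rational(2^k, factorial(n))
      expect_true(lhs == prob_cladogram(label_shape(shp))$fun)
    }
  }
})

test_that("the history mass of a single cladogram multiplies its step weights", {
  h <- enumerate_histories(4, "1/3")
  # total over cladograms equals 1 as well
  tot <- rational(0)
  for (nw in h$cladogram_newick) {
    tot <- tot + history_mass(h, parse_newick(nw))
  }
  expect_true(tot == rational(1))
  # the caterpillar grown 1,2,3,4 by always splitting the newest pendant arc
  # has some alpha-steps recorded; masses are products of a/(l-a), (1-a)/(l-a)
  m <- history_mass(h, parse_newick("(((1,2),3),4);"))
  expect_s3_class(m, "alpha_rational")
})

test_that("symbolic history masses at n = 5 include the worked shape value", {
  h <- enumerate_histories(5)
  expect_true(history_mass(h, fig4_shape()) == parse_alpha_fun("2*(1-a)/(4-a)"))
})

test_that("growing is deterministic given a seed and respects alpha limits", {
  t1 <- grow_cladogram(8, alpha = 0.3, seed = 99)
  t2 <- grow_cladogram(8, alpha = 0.3, seed = 99)
  expect_true(tree_equal(t1, t2))
  expect_identical(write_newick(grow_cladogram(2, alpha = 0.7, seed = 1)), "(1,2);")
  # alpha = 0: pendant attachments only, i.e. the Yule process; every grown
  # tree at alpha = 1 is a caterpillar for small n?  No: alpha = 1 forbids
  # pendant attachments, so n = 3 must put leaf 3 above the root or on the
  # single internal arc -- with n = 3 only the root position exists.
  expect_identical(write_newick(grow_cladogram(3, alpha = 1, seed = 3)),
                   write_newick(parse_newick("((1,2),3);")))
  set.seed(31)
  draws <- replicate(50, write_newick(shape_of(grow_cladogram(6, alpha = 0))))
  expect_true(all(nchar(draws) > 0))
})

test_that("sampled shape frequencies match the exact law (chi-square)", {
  N <- 20000
  for (a in c("0", "1/2")) {
    set.seed(417)
    tab <- new.env(parent = emptyenv())
    for (i in seq_len(N)) {
      key <- write_newick(sample_from_model(5, a, target = "shape"))
      tab[[key]] <- (if (is.null(tab[[key]])) 0L else tab[[key]]) + 1L
    }
    shapes <- enumerate_shapes(5)
    p <- vapply(shapes, function(s) as.numeric(evaluate_at(prob_shape(s)$fun, a)),
                numeric(1))
    obs <- vapply(shapes, function(s) {
      v <- tab[[write_newick(s)]]
      if (is.null(v)) 0 else as.numeric(v)
    }, numeric(1))
    keep <- p > 0
    x2 <- sum((obs[keep] - N * p[keep])^2 / (N * p[keep]))
    pval <- pchisq(x2, df = sum(keep) - 1, lower.tail = FALSE)
    expect_gt(pval, 1e-4)
    expect_equal(sum(obs), N)
  }
})

test_that("sampling cladograms relabels uniformly (n = 3 exact check)", {
  N <- 6000
  set.seed(91)
  counts <- c(0, 0, 0)
  keys <- vapply(enumerate_cladograms(3), write_newick, character(1))
  for (i in seq_len(N)) {
    k <- write_newick(sample_from_model(3, "1/2", target = "cladogram"))
    counts[match(k, keys)] <- counts[match(k, keys)] + 1
  }
  # each of the three cladograms has probability 1/3
  x2 <- sum((counts - N / 3)^2 / (N / 3))
  expect_gt(pchisq(x2, df = 2, lower.tail = FALSE), 1e-4)
})

test_that("identical seeds give identical sample sequences", {
  set.seed(123)
  a <- replicate(5, write_newick(sample_from_model(6, 0.4)))
  set.seed(123)
  b <- replicate(5, write_newick(sample_from_model(6, 0.4)))
  expect_identical(a, b)
})
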