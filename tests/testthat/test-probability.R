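# The four distributions, limit laws, recurrences, and the published-formula
# comparator.

test_that("the worked 8-leaf cladogram probability is exact", {
  p <- prob_cladogram(t_tilde())
  target <- parse_alpha_fun("(1-a)^2*(2-a)/(126*(3-a)*(5-a)*(6-a)*(7-a))")
  expect_true(p$fun == target)
  expect_true(evaluate_at(p$fun, "1/2") == rational(1, 135135))
  expect_true(prob_cladogram(t_tilde(), "1/2")$value == rational(1, 135135))
})

test_that("small worked examples evaluate by hand", {
  expect_true(prob_cladogram(parse_newick("(1,2);"))$fun == parse_alpha_fun("1"))
  for (t in enumerate_cladograms(3)) {
    expect_true(prob_cladogram(t)$fun == parse_alpha_fun("1/3"))
  }
  # n = 1 conventions
  one <- parse_newick("1;")
  expect_true(prob_cladogram(one)$fun == parse_alpha_fun("1"))
  expect_true(prob_shape(parse_newick(";", mode = "shape"))$fun == parse_alpha_fun("1"))
})

test_that("shape probabilities transport from cladograms", {
  expect_true(prob_shape(fig4_shape())$fun == parse_alpha_fun("2*(1-a)/(4-a)"))
  expect_true(prob_shape(parse_newick("(,);", mode = "shape"))$fun == parse_alpha_fun("1"))
  tts <- shape_of(t_tilde())
  expect_true(prob_shape(tts, "1/2")$value == rational(8, 429))   # 2520/135135
  for (n in 3:6) {
    for (s in enumerate_shapes(n)) {
      lhs <- prob_shape(s)$fun
      rhs <- prob_cladogram(label_shape(s))$fun * rational(preimage_count(s, "pi"))
      expect_true(lhs == rhs)
    }
  }
})

test_that("ordered variants divide by their preimage counts and agree with the q-product", {
  o2 <- parse_newick("(,);", mode = "ordered_shape")
  expect_true(prob_ordered_shape(o2)$fun == parse_alpha_fun("1"))
  for (nw in c("(1,2);", "(2,1);")) {
    oc <- parse_newick(nw, mode = "ordered_cladogram")
    expect_true(prob_ordered_cladogram(oc)$fun == parse_alpha_fun("1/2"))
  }
  # the internal cross-check between the transport route and the q-product
  # route runs on every call; exercise it across all ordered shapes to n = 7
  for (n in 2:7) {
    total <- parse_alpha_fun("0")
    for (o in enumerate_ordered_shapes(n)) {
      total <- total + prob_ordered_shape(o)$fun
    }
    expect_true(total == parse_alpha_fun("1"))
  }
})

test_that("limit laws: uniform at alpha = 1/2 and Yule at alpha = 0", {
  expect_true(prob_uniform(8) == rational(1, 135135))
  expect_true(prob_yule(parse_newick(NWK_CAT4)) == rational(1, 18))
  expect_true(prob_yule(parse_newick(NWK_BAL4)) == rational(1, 9))
  expect_true(prob_yule(t_tilde()) == rational(1, 39690))
  # the Yule law is a probability distribution: 12 caterpillars + 3 balanced
  tot <- rational(0)
  for (t in enumerate_cladograms(4)) tot <- tot + prob_yule(t)
  expect_true(tot == rational(1))
  for (n in 3:6) {
    for (t in enumerate_cladograms(n)) {
      expect_true(prob_cladogram(t, "1/2", symbolic = FALSE)$value == prob_uniform(n))
      expect_true(prob_cladogram(t, 0, symbolic = FALSE)$value == prob_yule(t))
    }
  }
})

test_that("probabilities normalize exactly at several alphas", {
  for (n in 3:6) {
    for (a in c("0", "1/4", "1/2", "3/4")) {
      tot <- rational(0)
      for_each_cladogram(n, function(t) {
        tot <<- tot + prob_cladogram(t, a, symbolic = FALSE)$value
      })
      expect_true(tot == rational(1))
    }
    # shapes, symbolically (covers every alpha at once)
    tot <- parse_alpha_fun("0")
    for (s in enumerate_shapes(n)) tot <- tot + prob_shape(s)$fun
    expect_true(tot == parse_alpha_fun("1"))
  }
  # alpha = 1 goes through the symbolic route (removable singularities)
  tot <- rational(0)
  for_each_cladogram(5, function(t) tot <<- tot + prob_cladogram(t, 1)$value)
  expect_true(tot == rational(1))
})

test_that("the rational fast path equals symbolic evaluation", {
  set.seed(3)
  for (i in 1:20) {
    t <- parse_newick(random_newick(sample(4:8, 1)))
    pr <- prob_cladogram(t, "1/3")
    expect_true(pr$value == evaluate_at(pr$fun, "1/3"))
  }
})

test_that("the published formula halves the counterexample and only it", {
  pub <- prob_cladogram_ford_published(t_tilde())
  target <- parse_alpha_fun("(1-a)^2*(2-a)/(252*(3-a)*(5-a)*(6-a)*(7-a))")
  expect_true(pub$fun == target)
  expect_true(prob_cladogram(t_tilde())$fun == pub$fun * 2)
  # agreement on every smaller tree (both formulas depend only on the shape)
  for (n in 2:7) {
    for (s in enumerate_shapes(n)) {
      t <- label_shape(s)
      expect_true(prob_cladogram_ford_published(t)$fun == prob_cladogram(t)$fun)
    }
  }
  # at n = 8 the mass deficit is exactly the 2520 halved cladograms
  tot <- rational(0)
  for (s in enumerate_shapes(8)) {
    mult <- rational(preimage_count(s, "pi"))
    tot <- tot + mult * prob_cladogram_ford_published(label_shape(s), "1/4",
                                                      symbolic = FALSE)$value
  }
  expect_true(tot < rational(1))
  deficit <- rational(1260) * prob_cladogram(t_tilde(), "1/4", symbolic = FALSE)$value
  expect_true(rational(1) - tot == deficit)
})

test_that("the cladogram Markov recurrence holds with factor 2q/C(n,m)", {
  expect_true(markov_factor_cladogram(1, 2) == parse_alpha_fun("1"))
  bal4 <- parse_newick(NWK_BAL4)
  expect_true(prob_cladogram(bal4)$fun == parse_alpha_fun("(1-a)/(3*(3-a))"))
  expect_true(check_markov_cladogram(parse_newick("(1,2);"), parse_newick("(3,4);")))
  set.seed(77)
  for (i in 1:40) {
    m <- sample(1:4, 1); l <- sample(1:4, 1)
    t1 <- parse_newick(random_newick(m))
    t2 <- parse_newick(random_newick(l, labels = m + sample(l)))
    expect_true(check_markov_cladogram(t1, t2))               # symbolic
    for (a in c("0", "1/3", "1/2", "1")) {
      expect_true(check_markov_cladogram(t1, t2, a))
    }
  }
})

test_that("the ordered-shape Markov recurrence holds with factor q", {
  for (m in 1:3) for (l in 1:3) {
    for (o1 in enumerate_ordered_shapes(m)) {
      for (o2 in enumerate_ordered_shapes(l)) {
        expect_true(check_ordered_markov(o1, o2))
      }
    }
  }
})

test_that("no Markov recurrence exists for unordered shapes", {
  demo <- demonstrate_no_shape_markov(6)
  expect_false(tree_equal(demo$t1, demo$t2))
  expect_identical(symmetric_branch_count(demo$t1), symmetric_branch_count(demo$t2))
  expect_true(demo$ratio_same == q_alpha(6, 6))
  expect_true(demo$ratio_diff == 2 * q_alpha(6, 6))
  expect_false(demo$ratio_same == demo$ratio_diff)
  expect_output(print(demo), "no factor")
})
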