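# The four probability distributions of the alpha-model, their limit laws,
# the Markov branching recurrences, and the published-formula comparator.
#
# Everything reduces to the product formula
#   P(T) = 2^(n-1) / (n! * Gamma_alpha(n)) * prod_{(a,b) in NS(T)} phi_alpha(a,b)
# for cladograms, together with the transport factors n!/2^k, 2^(n-1) and
# 2^(n-1-k) between the four kinds of trees.  Internally the product is kept
# integral by working with 2*phi, whose coefficients are integers:
#   P(T) = prod(2*phi) / (n! * Gamma_alpha(n)).

new_alpha_prob <- function(fun, alpha, value = NULL) {
  if (is.null(value) && !is.null(fun) && !alpha_is_symbolic(alpha)) {
    value <- evaluate_at(fun, alpha)
  }
  structure(list(fun = fun, alpha = alpha, value = value),
            class = "alpha_prob")
}

#' @export
print.alpha_prob <- function(x, ...) {
  if (!is.null(x$fun)) cat("P =", format(x$fun), "\n")
  if (!is.null(x$value)) {
    cat(sprintf("at alpha = %s: %s\n", format(x$alpha),
                if (inherits(x$value, "alpha_rational")) format(x$value)
                else format(x$value, digits = 15)))
  }
  invisible(x)
}

#' @export
as.double.alpha_prob <- function(x, ...) {
  if (!is.null(x$value)) return(as.numeric(x$value))
  stop("symbolic probability: fix alpha to obtain a number", call. = FALSE)
}

# product over the splits of the integer polynomial 2*phi
prod_phi2_poly <- function(splits) {
  P <- 1
  for (i in seq_len(nrow(splits))) P <- pmul(P, phi2_poly(splits[i, 1], splits[i, 2]))
  P
}

# product over the splits of 2*phi evaluated at p/q: unreduced pair
prod_phi2_rat <- function(splits, p, q) {
  num <- 1
  for (i in seq_len(nrow(splits))) {
    num <- imul(num, phi2_rat(splits[i, 1], splits[i, 2], p, q)[1])
  }
  c(num, ipow(q, nrow(splits)))
}

# P = prod(2 phi) / (divisor * Gamma_alpha(n)), symbolically
prob_fun_from_splits <- function(splits, n, divisor, extra_pow2 = 0) {
  num <- prod_phi2_poly(splits)
  if (extra_pow2 > 0) num <- pscale(num, ipow(2, extra_pow2))
  rf_make(num, pscale(gamma_alpha(n)$num, divisor))
}

# same thing at the exact rational alpha = p/q; NULL when Gamma vanishes
# (alpha = 1), in which case the caller falls back to the symbolic route
prob_value_from_splits <- function(splits, n, divisor, p, q, extra_pow2 = 0) {
  g <- gamma_rat(n, p, q)
  if (g[1] == 0) return(NULL)
  pr <- prod_phi2_rat(splits, p, q)
  num <- if (extra_pow2 > 0) imul(pr[1], ipow(2, extra_pow2)) else pr[1]
  # the q-powers of prod(2 phi) and Gamma cancel exactly
  new_rational(rat_norm(num, imul(divisor, g[1])))
}

# shared driver for the product-formula distributions
prob_product_formula <- function(t, alpha, divisor, extra_pow2, symbolic) {
  alpha <- alpha_value(alpha)
  splits <- numerical_splits(t)
  n <- t$n
  fun <- NULL
  value <- NULL
  if (alpha$kind == "rational") {
    value <- prob_value_from_splits(splits, n, divisor, alpha$p, alpha$q, extra_pow2)
    if (is.null(value)) symbolic <- TRUE  # removable singularity at alpha = 1
  }
  if (symbolic || alpha$kind != "rational") {
    fun <- prob_fun_from_splits(splits, n, divisor, extra_pow2)
  }
  new_alpha_prob(fun, alpha, value)
}

#' Probability of a cladogram under the alpha-model
#'
#' The corrected closed form
#' `P(T) = 2^(n-1) / (n! Gamma_alpha(n)) * prod_{(a,b) in NS(T)} phi_alpha(a, b)`,
#' which depends on `T` only through its multiset of numerical splits.  At
#' `alpha = 1/2` every cladogram has probability `1/(2n-3)!!` (the uniform/PDA
#' model); at `alpha = 0` the Yule probability results.
#'
#' @param t a `cladogram`.
#' @param alpha an [alpha_value()] or anything it accepts: `"sym"` (default),
#'   `"p/q"`, a number.
#' @param symbolic keep the symbolic rational function alongside the numeric
#'   value when alpha is fixed?  Setting `FALSE` skips the polynomial work in
#'   tight enumeration loops.  (At `alpha = 1`, where the plain product
#'   formula is a removable `0/0`, the symbolic route is used regardless.)
#' @return An `alpha_prob` with fields `fun` (an `alpha_fun` or `NULL`) and
#'   `value` (an exact [rational()] for rational alpha, a double for float
#'   alpha, `NULL` for symbolic alpha).
#' @examples
#' tt <- parse_newick("(((1,2),(3,4)),(((5,6),7),8));")
#' prob_cladogram(tt)            # (1-a)^2*(2-a)/(126*(3-a)*(5-a)*(6-a)*(7-a))
#' prob_cladogram(tt, "1/2")     # 1/135135
#' @export
prob_cladogram <- function(t, alpha = "sym", symbolic = TRUE) {
  stopifnot(inherits(t, "alpha_tree"))
  if (!t$kind %in% c("cladogram", "shape")) {
    stop("prob_cladogram expects an unordered tree", call. = FALSE)
  }
  prob_product_formula(t, alpha, divisor = ifactorial(t$n), extra_pow2 = 0,
                       symbolic = symbolic)
}

#' Probability of a tree shape under the alpha-model
#'
#' `P*(T*) = 2^(n-k-1) / Gamma_alpha(n) * prod phi_alpha(a, b)`, where `k` is
#' the number of symmetric branch points: the probability of any cladogram
#' with that shape times the `n!/2^k` cladograms carrying it.
#'
#' @param t a `tree_shape` (a `cladogram` is accepted and its shape taken).
#' @inheritParams prob_cladogram
#' @return An `alpha_prob`.
#' @examples
#' s <- parse_newick("((,),((,),));", mode = "shape")
#' prob_shape(s)  # 2*(1-a)/(4-a)
#' @export
prob_shape <- function(t, alpha = "sym", symbolic = TRUE) {
  stopifnot(inherits(t, "alpha_tree"))
  if (kind_is_ordered(t$kind)) stop("prob_shape expects an unordered tree", call. = FALSE)
  k <- symmetric_branch_count(t)
  prob_product_formula(t, alpha, divisor = ipow(2, k), extra_pow2 = 0,
                       symbolic = symbolic)
}

#' Probabilities of ordered cladograms and ordered tree shapes
#'
#' The alpha-model law is transported to the ordered kinds by dividing by the
#' preimage counts: an ordered cladogram has probability `P(T)/2^(n-1)`; an
#' ordered tree shape has probability `P*(T*)/2^(n-1-k)`, which also equals
#' the product of `q_alpha(a, b)` over its numerical splits.  For ordered
#' shapes both routes are computed and must agree exactly (a violation would
#' indicate an internal inconsistency and raises an error).
#'
#' @param t an `ordered_cladogram` / `ordered_tree_shape`.
#' @inheritParams prob_cladogram
#' @return An `alpha_prob`.
#' @examples
#' o <- parse_newick("((,),);", mode = "ordered_shape")
#' prob_ordered_shape(o)
#' @export
prob_ordered_cladogram <- function(t, alpha = "sym", symbolic = TRUE) {
  stopifnot(inherits(t, "ordered_cladogram"))
  base <- prob_cladogram(forget_order(t), alpha, symbolic)
  scale_prob(base, 1, ipow(2, t$n - 1))
}

#' @rdname prob_ordered_cladogram
#' @export
prob_ordered_shape <- function(t, alpha = "sym", symbolic = TRUE) {
  stopifnot(inherits(t, "ordered_tree_shape"))
  alpha <- alpha_value(alpha)
  shape <- forget_order(t)
  k <- symmetric_branch_count(shape)
  transported <- scale_prob(prob_shape(shape, alpha, symbolic),
                            1, ipow(2, t$n - 1 - k))
  # independent route: product of q_alpha over the splits
  splits <- numerical_splits(t)
  if (!is.null(transported$fun)) {
    prod_q <- rf_const(1)
    for (i in seq_len(nrow(splits))) {
      prod_q <- rf_mul(prod_q, q_alpha(splits[i, 1], splits[i, 2]))
    }
    if (!rf_equal(prod_q, transported$fun)) {
      stop("internal invariant violation: the transport and product routes ",
           "for the ordered-shape probability disagree", call. = FALSE)
    }
  } else if (inherits(transported$value, "alpha_rational")) {
    acc <- c(1, 1)
    ok <- TRUE
    for (i in seq_len(nrow(splits))) {
      qv <- tryCatch(evaluate_at(q_alpha(splits[i, 1], splits[i, 2]), alpha),
                     error = function(e) NULL)
      if (is.null(qv)) { ok <- FALSE; break }  # pole: route unavailable here
      acc <- rat_mul_(acc, c(qv$num, qv$den))
    }
    if (ok && rat_cmp_(acc, c(transported$value$num, transported$value$den)) != 0) {
      stop("internal invariant violation: the transport and product routes ",
           "for the ordered-shape probability disagree", call. = FALSE)
    }
  }
  transported
}

# multiply an alpha_prob by the exact rational p/q
scale_prob <- function(pr, p, q) {
  fun <- if (!is.null(pr$fun)) rf_mul(pr$fun, rf_const(p, q)) else NULL
  value <- pr$value
  if (!is.null(value)) {
    value <- if (inherits(value, "alpha_rational")) {
      new_rational(rat_mul_(c(value$num, value$den), c(p, q)))
    } else {
      value * p / q
    }
  }
  new_alpha_prob(fun, pr$alpha, value)
}

#' Limit laws: uniform (PDA) and Yule probabilities
#'
#' `prob_uniform(n)` is the common probability `1/(2n-3)!!` of every cladogram
#' on `n` leaves under the uniform (PDA) model, the alpha-model at
#' `alpha = 1/2`.  `prob_yule(t)` is the Yule probability
#' `2^(n-1)/n! * prod_v 1/(kappa(v)-1)` (product over internal nodes), the
#' alpha-model at `alpha = 0`.
#'
#' @param n leaf count (`n >= 1`).
#' @param t a `cladogram` (or `tree_shape`; the value depends only on the
#'   shape).
#' @return An exact [rational()].
#' @examples
#' prob_uniform(8)                                         # 1/135135
#' prob_yule(parse_newick("(((1,2),(3,4)),(((5,6),7),8));")) # 1/39690
#' @export
prob_uniform <- function(n) {
  stopifnot(length(n) == 1, n == round(n), n >= 1)
  if (n < 2) return(rational(1))
  rational(1, idouble_factorial_odd(2 * n - 3))
}

#' @rdname prob_uniform
#' @export
prob_yule <- function(t) {
  stopifnot(inherits(t, "alpha_tree"))
  if (kind_is_ordered(t$kind)) stop("prob_yule expects an unordered tree", call. = FALSE)
  n <- t$n
  den <- ifactorial(n)
  acc <- c(ipow(2, max(n - 1, 0)), den)
  rec <- function(node) {
    if (node$leaf) return(invisible())
    acc <<- rat_mul_(acc, c(1, node$n - 1))
    rec(node$kids[[1]]); rec(node$kids[[2]])
  }
  rec(t$root)
  new_rational(acc)
}

#' The published (erroneous) cladogram probability, as a comparator
#'
#' Implements the product formula as originally published:
#' `P(T) = 2^k/n! * prod qhat_alpha(a, b)`, equivalently
#' `2^(k+m) / (n! Gamma_alpha(n)) * prod phi_alpha(a, b)` with `m` the number
#' of internal nodes whose children carry different numbers of leaves.  It
#' agrees with [prob_cladogram()] exactly when every internal node with
#' equal child leaf counts is a symmetric branch point (`k + m = n - 1`), and
#' otherwise undercounts by a power of 2 -- the smallest counterexample has 8
#' leaves, where the published value is exactly half the correct one and the
#' probabilities over all 135135 cladograms no longer sum to 1.  Shipped only
#' for reproducing that discrepancy; never used by the other functions.
#'
#' @inheritParams prob_cladogram
#' @return An `alpha_prob`.
#' @examples
#' tt <- parse_newick("(((1,2),(3,4)),(((5,6),7),8));")
#' prob_cladogram_ford_published(tt, "1/2")  # 1/270270, half the true value
#' @export
prob_cladogram_ford_published <- function(t, alpha = "sym", symbolic = TRUE) {
  stopifnot(inherits(t, "alpha_tree"))
  if (kind_is_ordered(t$kind)) {
    stop("prob_cladogram_ford_published expects an unordered tree", call. = FALSE)
  }
  splits <- numerical_splits(t)
  k <- symmetric_branch_count(t)
  m <- sum(splits[, 1] != splits[, 2])
  n <- t$n
  # prod(2 phi) * 2^(k+m) / (2^(n-1) n! Gamma); keep the constant integral
  deficit <- (n - 1) - (k + m)   # >= 0; 0 iff the formula is correct on t
  prob_product_formula(t, alpha, divisor = imul(ifactorial(n), ipow(2, deficit)),
                       extra_pow2 = 0, symbolic = symbolic)
}

#' Markov branching recurrence for cladograms
#'
#' The corrected cladogram law satisfies
#' `P(T_m * T_(n-m)) = [2 q_alpha(m, n-m) / C(n, m)] * P(T_m) * P(T_(n-m))`
#' for the root join of cladograms on disjoint label sets.
#' `markov_factor_cladogram()` returns the bracketed factor;
#' `check_markov_cladogram()` verifies the identity exactly for a concrete
#' pair (symbolically, or at a fixed alpha).
#'
#' @param m,n sizes: the parts carry `m` and `n - m` leaves, `0 < m < n`.
#' @return `markov_factor_cladogram()`: an `alpha_fun`;
#'   `check_markov_cladogram()`: `TRUE`/`FALSE`.
#' @examples
#' markov_factor_cladogram(1, 2)  # 1
#' @export
markov_factor_cladogram <- function(m, n) {
  stopifnot(m == round(m), n == round(n), m >= 1, n > m)
  rf_mul(rf_const(2, ichoose(n, m)), q_alpha(m, n - m))
}

#' @rdname markov_factor_cladogram
#' @param t1,t2 cladograms on disjoint label sets.
#' @inheritParams prob_cladogram
#' @export
check_markov_cladogram <- function(t1, t2, alpha = "sym") {
  alpha <- alpha_value(alpha)
  n <- t1$n + t2$n
  joined <- root_join(t1, t2)
  fac <- markov_factor_cladogram(t1$n, n)
  compare_prob_identity(prob_cladogram(joined, alpha),
                        prob_cladogram(t1, alpha), prob_cladogram(t2, alpha),
                        fac, alpha)
}

#' Markov branching recurrence for ordered tree shapes
#'
#' The ordered-shape law satisfies the clean recurrence
#' `P(T* join T'*) = q_alpha(m, n-m) * P(T*) * P(T'*)`; this verifies it for
#' a concrete pair.  No analogous recurrence exists at the unordered shape
#' level: see [demonstrate_no_shape_markov()].
#'
#' @param t1,t2 `ordered_tree_shape` objects.
#' @inheritParams prob_cladogram
#' @return `TRUE`/`FALSE`.
#' @export
check_ordered_markov <- function(t1, t2, alpha = "sym") {
  stopifnot(inherits(t1, "ordered_tree_shape"), inherits(t2, "ordered_tree_shape"))
  alpha <- alpha_value(alpha)
  joined <- root_join(t1, t2)
  fac <- q_alpha(t1$n, t2$n)
  compare_prob_identity(prob_ordered_shape(joined, alpha),
                        prob_ordered_shape(t1, alpha),
                        prob_ordered_shape(t2, alpha),
                        fac, alpha)
}

# lhs == fac * p1 * p2, in whatever mode alpha dictates
compare_prob_identity <- function(lhs, p1, p2, fac, alpha) {
  if (alpha_is_symbolic(alpha)) {
    return(rf_equal(lhs$fun, rf_mul(fac, rf_mul(p1$fun, p2$fun))))
  }
  fv <- evaluate_at(fac, alpha)
  if (inherits(lhs$value, "alpha_rational")) {
    rhs <- rat_mul_(c(fv$num, fv$den),
                    rat_mul_(c(p1$value$num, p1$value$den),
                             c(p2$value$num, p2$value$den)))
    return(rat_cmp_(c(lhs$value$num, lhs$value$den), rhs) == 0)
  }
  isTRUE(all.equal(as.numeric(lhs$value),
                   fv * as.numeric(p1$value) * as.numeric(p2$value),
                   tolerance = 1e-12))
}

#' Why no Markov recurrence exists for unordered tree shapes
#'
#' Exhibits two distinct `m`-leaf tree shapes with the same number of
#' symmetric branch points, and computes exactly the probabilities of the
#' four root joins built from them.  The ratio `P*(T join T)/P*(T)^2` equals
#' `q_alpha(m, m)` while `P*(T join T') / (P*(T) P*(T'))` equals
#' `2 q_alpha(m, m)`: no single factor `Q(m, m)` can reproduce both, so the
#' unordered shape law is not Markov branching.
#'
#' @param m leaf count of each part; needs `m >= 4` so that two distinct
#'   shapes with equal symmetric-branch-point count exist (default 6).
#' @return An object with the pair, all four probabilities and the two
#'   implied factors (all exact); printing lays out the argument.
#' @examples
#' demonstrate_no_shape_markov(6)
#' @export
demonstrate_no_shape_markov <- function(m = 6) {
  stopifnot(m == round(m))
  if (m < 4) stop("need m >= 4: smaller m admits no suitable shape pair", call. = FALSE)
  shapes <- enumerate_shapes(m)
  ks <- vapply(shapes, symmetric_branch_count, integer(1))
  pair <- NULL
  for (i in seq_along(shapes)) {
    j <- which(ks == ks[i])
    j <- j[j > i]
    if (length(j)) { pair <- c(i, j[1]); break }
  }
  if (is.null(pair)) stop("no equal-k shape pair found", call. = FALSE)
  t1 <- shapes[[pair[1]]]; t2 <- shapes[[pair[2]]]
  p1 <- prob_shape(t1)$fun
  p2 <- prob_shape(t2)$fun
  p11 <- prob_shape(root_join(t1, t1))$fun
  p12 <- prob_shape(root_join(t1, t2))$fun
  q <- q_alpha(m, m)
  r_same <- rf_div(p11, rf_mul(p1, p1))
  r_diff <- rf_div(p12, rf_mul(p1, p2))
  if (!rf_equal(r_same, q) || !rf_equal(r_diff, rf_mul(rf_const(2), q))) {
    stop("internal invariant violation: unexpected Markov ratios", call. = FALSE)
  }
  structure(list(m = m, k = ks[pair[1]], t1 = t1, t2 = t2,
                 p1 = p1, p2 = p2, p_same = p11, p_diff = p12,
                 ratio_same = r_same, ratio_diff = r_diff, q = q),
            class = "no_shape_markov_demo")
}

#' @export
print.no_shape_markov_demo <- function(x, ...) {
  cat(sprintf("Two distinct %d-leaf shapes, both with k = %d symmetric branch points:\n",
              x$m, x$k))
  cat("  T  =", write_newick(x$t1), "  P*(T)  =", format(x$p1), "\n")
  cat("  T' =", write_newick(x$t2), "  P*(T') =", format(x$p2), "\n")
  cat("Root joins:\n")
  cat("  P*(T*T)  =", format(x$p_same), "\n")
  cat("  P*(T*T') =", format(x$p_diff), "\n")
  cat("Implied Markov factors:\n")
  cat("  P*(T*T) / P*(T)^2      =", format(x$ratio_same), " (= q_alpha)\n")
  cat("  P*(T*T') / (P*(T)P*(T')) =", format(x$ratio_diff), " (= 2 q_alpha)\n")
  cat("These differ, so no factor Q(m, m) can close a shape-level recurrence.\n")
  invisible(x)
}
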