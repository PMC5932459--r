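# The sequential leaf-addition process.
#
# Starting from the cherry on {1,2}, leaf m is attached, for m = 3..n, to one
# of the 2(m-1)-1 positions of the current tree: a pendant arc with weight
# (1-alpha), an internal arc or the position above the root with weight alpha;
# the weights at leaf count l total l*(1-alpha) + (l-1)*alpha = l - alpha, so
# each step is a probability distribution for every alpha in [0,1].  A history
# with i alpha-steps has probability
#   alpha^i (1-alpha)^(n-2-i) / prod_{l=2}^{n-1} (l - alpha),
# and every cladogram on {1..n} arises from exactly one history, which makes
# the exhaustive enumeration of histories a brute-force oracle for all four
# distributions.

history_denominator <- function(n) {
  P <- 1
  if (n >= 3) for (l in 2:(n - 1)) P <- pmul(P, c(l, -1))
  P
}

# exact mass of a bundle of histories given the counts c[i+1] = number of
# histories with i alpha-steps, as an alpha_fun (alpha symbolic) or rational
history_mass_fun <- function(counts, n) {
  num <- double(0)
  steps <- n - 2
  for (i in seq_along(counts)) {
    if (counts[i] == 0) next
    # counts[i] * a^(i-1) * (1-a)^(steps-i+1)
    term <- counts[i]
    P <- c(rep(0, i - 1), 1)
    for (j in seq_len(steps - i + 1)) P <- pmul(P, c(1, -1))
    num <- padd(num, pscale(P, term))
  }
  rf_make(num, history_denominator(n))
}

history_mass_rat <- function(counts, n, p, q) {
  steps <- n - 2
  num <- 0
  for (i in seq_along(counts)) {
    if (counts[i] == 0) next
    term <- imul(counts[i], imul(ipow(p, i - 1), ipow(q - p, steps - i + 1)))
    num <- iadd(num, term)
  }
  den <- 1
  if (n >= 3) for (l in 2:(n - 1)) den <- imul(den, l * q - p)
  new_rational(rat_norm(num, den))
}

#' Exhaustively enumerate the growth histories on n leaves
#'
#' Runs every sequence of attachment choices of the leaf-addition process,
#' recording for each resulting cladogram (each arises exactly once) and each
#' tree shape the exact probability mass of its histories.  Serves as the
#' brute-force oracle against which the closed-form probabilities are checked:
#' the mass of a shape is its probability `P*`, and the mass of a cladogram
#' times `n!/2^k` recovers `P*` of its shape as well.
#'
#' @param n leaf count, `2 <= n <= 8` (135135 histories at `n = 8`).
#' @param alpha an [alpha_value()]: symbolic (default) or fixed.
#' @return A list with components `n`, `alpha`, `n_histories`,
#'   `shapes` (data frame: `newick`, `k`, one row per shape) and
#'   `shape_mass` (list of exact masses, parallel to `shapes`), plus
#'   `cladogram_newick` and `cladogram_alpha_steps` giving, for every
#'   cladogram, the number of alpha-steps of its unique history (from which
#'   its mass follows).  Use [history_mass()] to read off masses.
#' @examples
#' h <- enumerate_histories(5)
#' format(history_mass(h, parse_newick("((((,),),),(,));", "shape")))
#' @export
enumerate_histories <- function(n, alpha = "sym") {
  stopifnot(length(n) == 1, n == round(n))
  if (n < 2 || n > 8) stop("enumerate_histories supports 2 <= n <= 8", call. = FALSE)
  alpha <- alpha_value(alpha)
  steps <- n - 2
  shape_counts <- new.env(parent = emptyenv())
  n_total <- idouble_factorial_odd(2 * n - 3)
  clad_newick <- character(n_total)
  clad_steps <- integer(n_total)
  nh <- 0L
  visit <- function(root, m, i) {
    if (m == n) {
      nh <<- nh + 1L
      tr <- new_tree(root, "cladogram")
      clad_newick[[nh]] <<- write_newick(tr)
      clad_steps[[nh]] <<- i
      enc <- shape_encoding(root)
      cnt <- shape_counts[[enc]]
      if (is.null(cnt)) cnt <- integer(steps + 1L)
      cnt[i + 1L] <- cnt[i + 1L] + 1L
      shape_counts[[enc]] <<- cnt
      return(invisible())
    }
    positions <- collect_positions(root)
    l <- m  # current leaf count
    for (idx in seq_along(positions)) {
      # the first l positions are pendant arcs (weight 1-alpha), the rest
      # internal arcs and the new root (weight alpha)
      di <- if (idx <= l) 0L else 1L
      visit(insert_leaf_at(root, positions[[idx]], as.character(m + 1L)),
            m + 1L, i + di)
    }
  }
  cherry <- new_inode(new_leaf("1"), new_leaf("2"))
  visit(cherry, 2L, 0L)

  encs <- sort(ls(shape_counts))
  shapes_df <- data.frame(newick = character(length(encs)),
                          k = integer(length(encs)),
                          stringsAsFactors = FALSE)
  mass <- vector("list", length(encs))
  counts <- vector("list", length(encs))
  for (s in seq_along(encs)) {
    cnt <- shape_counts[[encs[s]]]
    counts[[s]] <- cnt
    shp <- shape_from_encoding(encs[s])
    shapes_df$newick[s] <- write_newick(shp)
    shapes_df$k[s] <- symmetric_branch_count(shp)
    mass[[s]] <- switch(alpha$kind,
                        symbolic = history_mass_fun(cnt, n),
                        rational = history_mass_rat(cnt, n, alpha$p, alpha$q),
                        float = evaluate_at(history_mass_fun(cnt, n), alpha))
  }
  structure(list(n = n, alpha = alpha, n_histories = nh,
                 shapes = shapes_df, shape_encoding = encs,
                 shape_counts = counts, shape_mass = mass,
                 cladogram_newick = clad_newick,
                 cladogram_alpha_steps = clad_steps),
            class = "alpha_histories")
}

# rebuild a tree shape from its canonical parenthesis encoding
shape_from_encoding <- function(enc) {
  chars <- strsplit(enc, "")[[1]]
  pos <- 1L
  rec <- function() {
    if (chars[pos] == "x") {
      pos <<- pos + 1L
      return(new_leaf())
    }
    stopifnot(chars[pos] == "(")
    pos <<- pos + 1L
    a <- rec(); b <- rec()
    stopifnot(chars[pos] == ")")
    pos <<- pos + 1L
    new_inode(a, b)
  }
  new_tree(rec(), "shape")
}

#' @export
print.alpha_histories <- function(x, ...) {
  cat(sprintf("growth histories on %d leaves (%d histories, %d shapes), alpha = %s\n",
              x$n, x$n_histories, nrow(x$shapes), format(x$alpha)))
  invisible(x)
}

#' Exact history mass of a cladogram or shape
#'
#' Reads the brute-force probability of a tree out of an
#' [enumerate_histories()] result: for a shape, the total mass of all growth
#' histories producing that shape (its probability `P*`); for a cladogram,
#' the mass of its unique history (the chain probability `P'`, which is not
#' the cladogram's model probability `P` -- that follows by transporting the
#' shape mass, see [preimage_count()]).
#'
#' @param h an `alpha_histories` object.
#' @param t a `tree_shape` or `cladogram` with `h$n` leaves.
#' @return An `alpha_fun` (symbolic alpha), [rational()] (rational alpha) or
#'   double (float alpha); zero if the tree never occurs.
#' @export
history_mass <- function(h, t) {
  stopifnot(inherits(h, "alpha_histories"), inherits(t, "alpha_tree"))
  if (t$n != h$n) stop("tree size does not match the enumeration", call. = FALSE)
  if (t$kind == "shape") {
    idx <- match(shape_encoding(t$root), h$shape_encoding)
    if (is.na(idx)) {
      return(zero_mass(h))
    }
    return(h$shape_mass[[idx]])
  }
  if (t$kind != "cladogram") stop("history_mass expects a shape or cladogram", call. = FALSE)
  idx <- match(write_newick(t), h$cladogram_newick)
  if (is.na(idx)) return(zero_mass(h))
  i <- h$cladogram_alpha_steps[idx]
  cnt <- integer(h$n - 1L)
  cnt[i + 1L] <- 1L
  switch(h$alpha$kind,
         symbolic = history_mass_fun(cnt, h$n),
         rational = history_mass_rat(cnt, h$n, h$alpha$p, h$alpha$q),
         float = evaluate_at(history_mass_fun(cnt, h$n), h$alpha))
}

zero_mass <- function(h) {
  switch(h$alpha$kind,
         symbolic = rf_const(0),
         rational = rational(0),
         float = 0)
}

#' Grow a random cladogram under the alpha-model
#'
#' Runs the leaf-addition process once: at leaf count `l` the next leaf
#' attaches to a specific pendant arc with probability `(1-alpha)/(l-alpha)`
#' and to a specific internal arc or above the root with probability
#' `alpha/(l-alpha)`.  The resulting cladogram on `{1..n}` is distributed
#' according to the chain law `P'` (not `P`; see [sample_from_model()] for
#' draws from the model distributions proper).  Deterministic given `seed`.
#'
#' @param n leaf count, `n >= 1`.
#' @param alpha a numeric alpha in `[0, 1]` (rational strings accepted);
#'   `alpha = 1` is supported (pendant weights vanish, attachments are
#'   uniform over internal arcs and the root position).
#' @param seed optional integer seed; if `NULL`, the current RNG state is
#'   used and advanced.
#' @return A `cladogram`.
#' @examples
#' write_newick(grow_cladogram(8, alpha = 0.3, seed = 1))
#' @export
grow_cladogram <- function(n, alpha, seed = NULL) {
  stopifnot(length(n) == 1, n == round(n), n >= 1)
  av <- alpha_value(alpha)
  if (alpha_is_symbolic(av)) stop("sampling needs a numeric alpha", call. = FALSE)
  a <- if (av$kind == "rational") av$p / av$q else av$x
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  if (n == 1) return(new_tree(new_leaf("1"), "cladogram"))
  root <- new_inode(new_leaf("1"), new_leaf("2"))
  m <- 2L
  while (m < n) {
    l <- m
    w_pend <- l * (1 - a)
    w_int <- (l - 1) * a
    u <- stats::runif(1) * (w_pend + w_int)
    positions <- collect_positions(root)
    if (u < w_pend && w_pend > 0) {
      j <- min(floor(u / (1 - a)) + 1, l)      # uniform pendant arc
      path <- positions[[j]]
    } else {
      r <- stats::runif(1)
      j <- min(floor(r * (l - 1)) + 1, l - 1)  # uniform internal arc / root
      path <- positions[[l + j]]
    }
    root <- insert_leaf_at(root, path, as.character(m + 1L))
    m <- m + 1L
  }
  new_tree(root, "cladogram")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Draw from the alpha-model distributions
#'
#' Samples a tree shape or a cladogram with the model's exact law.  A shape is
#' the shape of one growth run (the growth chain transports to shapes without
#' correction).  A cladogram is a grown shape relabeled uniformly at random --
#' this is the model law `P`, which differs from the raw chain law `P'` of
#' [grow_cladogram()] because a shape with `k` symmetric branch points spreads
#' its mass over `n!/2^k` cladograms.
#'
#' @inheritParams grow_cladogram
#' @param target `"cladogram"` or `"shape"`.
#' @return An `alpha_tree` of the requested kind.
#' @examples
#' sample_from_model(5, alpha = "1/2", seed = 42, target = "shape")
#' @export
sample_from_model <- function(n, alpha, seed = NULL,
                              target = c("cladogram", "shape")) {
  target <- match.arg(target)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  grown <- grow_cladogram(n, alpha)
  shape <- shape_of(grown)
  if (target == "shape") return(shape)
  label_shape(shape, sample(n))
}
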