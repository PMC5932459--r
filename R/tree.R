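# Rooted bifurcating trees: shapes, cladograms, and their ordered variants.
#
# Nodes are plain recursive lists: a leaf is list(leaf = TRUE, n = 1, label),
# an internal node is list(leaf = FALSE, n, kids = list(left, right)).  A tree
# object wraps the root and records its kind.  Unordered kinds are stored in
# canonical child order (sorted by subtree leaf count, then by a canonical
# shape encoding, then by smallest descendant label), so structural equality
# coincides with isomorphism; ordered kinds keep the given child order.

new_leaf <- function(label = NA_character_) {
  list(leaf = TRUE, n = 1L, label = label)
}

new_inode <- function(left, right) {
  list(leaf = FALSE, n = left$n + right$n, kids = list(left, right))
}

TREE_KINDS <- c("shape", "cladogram", "ordered_shape", "ordered_cladogram")

kind_class <- function(kind) {
  switch(kind,
         shape = "tree_shape",
         cladogram = "cladogram",
         ordered_shape = "ordered_tree_shape",
         ordered_cladogram = "ordered_cladogram")
}

kind_is_ordered <- function(kind) kind %in% c("ordered_shape", "ordered_cladogram")
kind_is_labeled <- function(kind) kind %in% c("cladogram", "ordered_cladogram")

new_tree <- function(root, kind, canonicalize = TRUE) {
  kind <- match.arg(kind, TREE_KINDS)
  if (canonicalize && !kind_is_ordered(kind)) {
    root <- canonical_node(root, labeled = kind_is_labeled(kind))$node
  }
  structure(list(root = root, n = root$n, kind = kind),
            class = c(kind_class(kind), "alpha_tree"))
}

# label comparison: numeric when both labels are integers, else lexicographic
label_lt <- function(x, y) {
  xs <- suppressWarnings(as.numeric(x)); ys <- suppressWarnings(as.numeric(y))
  if (!is.na(xs) && !is.na(ys)) return(xs < ys)
  x < y
}

# Bottom-up canonicalization.  Returns the reordered node together with its
# shape encoding (a parenthesis string ignoring labels) and its minimal
# descendant label, the tie-break key for equal-shape siblings of cladograms.
canonical_node <- function(node, labeled) {
  if (node$leaf) {
    return(list(node = node, enc = "x", minlab = node$label))
  }
  a <- canonical_node(node$kids[[1]], labeled)
  b <- canonical_node(node$kids[[2]], labeled)
  swap <- FALSE
  na <- a$node$n; nb <- b$node$n
  if (na != nb) {
    swap <- na > nb
  } else if (a$enc != b$enc) {
    swap <- a$enc > b$enc
  } else if (labeled) {
    swap <- label_lt(b$minlab, a$minlab)
  }
  if (swap) { t <- a; a <- b; b <- t }
  minlab <- a$minlab
  if (labeled && !is.na(b$minlab) &&
      (is.na(minlab) || label_lt(b$minlab, minlab))) {
    minlab <- b$minlab
  }
  list(node = new_inode(a$node, b$node),
       enc = paste0("(", a$enc, b$enc, ")"),
       minlab = minlab)
}

# canonical shape encoding of an arbitrary (sub)tree, ignoring labels/order
shape_encoding <- function(node) {
  if (node$leaf) return("x")
  a <- shape_encoding(node$kids[[1]])
  b <- shape_encoding(node$kids[[2]])
  na <- node$kids[[1]]$n; nb <- node$kids[[2]]$n
  if (na > nb || (na == nb && a > b)) { t <- a; a <- b; b <- t }
  paste0("(", a, b, ")")
}

#' Number of leaves
#'
#' @param t an `alpha_tree`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(t) {
  stopifnot(inherits(t, "alpha_tree"))
  t$n
}

#' Leaf count below a node (kappa)
#'
#' Returns the number of leaf descendants of the node addressed by `path`, a
#' vector of child indices (1 = first child, 2 = second child) walked from the
#' root; the empty path addresses the root.
#'
#' @param t an `alpha_tree`.
#' @param path integer vector of child indices; `integer(0)` for the root.
#' @return A positive integer.
#' @examples
#' t <- parse_newick("((1,2),(3,((4,5),(6,7))));")
#' kappa(t)          # 7, the root
#' kappa(t, c(2, 2)) # the 4-leaf subtree
#' @export
kappa <- function(t, path = integer(0)) {
  stopifnot(inherits(t, "alpha_tree"))
  node <- t$root
  for (i in path) {
    if (node$leaf || !(i %in% c(1, 2))) {
      stop("invalid node path", call. = FALSE)
    }
    node <- node$kids[[i]]
  }
  node$n
}

#' Multiset of numerical splits
#'
#' Every internal node contributes the pair of leaf counts of its two child
#' subtrees: `(min, max)` for unordered trees, `(left, right)` in child order
#' for ordered trees.  The result is the multiset of these pairs, as a
#' two-column matrix with rows in a fixed sorted order (multiset semantics).
#'
#' @param t an `alpha_tree`.
#' @return An integer matrix of class `split_multiset` with columns `a`, `b`
#'   and one row per internal node.
#' @examples
#' numerical_splits(parse_newick("((1,2),(3,((4,5),(6,7))));"))
#' @export
numerical_splits <- function(t) {
  stopifnot(inherits(t, "alpha_tree"))
  ordered <- kind_is_ordered(t$kind)
  acc <- matrix(NA_real_, nrow = max(t$n - 1, 0), ncol = 2)
  dimnames(acc) <- list(NULL, c("a", "b"))
  i <- 0L
  rec2 <- function(node) {
    if (node$leaf) return(invisible())
    a <- node$kids[[1]]$n; b <- node$kids[[2]]$n
    if (!ordered && a > b) { tmp <- a; a <- b; b <- tmp }
    i <<- i + 1L
    acc[i, ] <<- c(a, b)
    rec2(node$kids[[1]]); rec2(node$kids[[2]])
  }
  rec2(t$root)
  acc <- acc[order(acc[, 1], acc[, 2]), , drop = FALSE]
  structure(acc, class = "split_multiset")
}

#' @export
print.split_multiset <- function(x, ...) {
  cat("{", paste(sprintf("(%d,%d)", x[, 1], x[, 2]), collapse = ", "), "}\n")
  invisible(x)
}

#' Number of symmetric branch points
#'
#' A symmetric branch point is an internal node whose two child subtrees are
#' isomorphic as (unordered, unlabeled) tree shapes.  Their count `k` controls
#' the preimage sizes of the forgetful maps: a shape with `k` symmetric branch
#' points underlies `n!/2^k` cladograms and `2^(n-1-k)` ordered shapes.
#'
#' @param t an `alpha_tree`.
#' @return A nonnegative integer.
#' @examples
#' symmetric_branch_count(parse_newick("(((1,2),(3,4)),(((5,6),7),8));")) # 4
#' @export
symmetric_branch_count <- function(t) {
  stopifnot(inherits(t, "alpha_tree"))
  k <- 0L
  rec <- function(node) {
    if (node$leaf) return("x")
    a <- rec(node$kids[[1]])
    b <- rec(node$kids[[2]])
    if (a == b) k <<- k + 1L
    na <- node$kids[[1]]$n; nb <- node$kids[[2]]$n
    if (na > nb || (na == nb && a > b)) { t2 <- a; a <- b; b <- t2 }
    paste0("(", a, b, ")")
  }
  rec(t$root)
  k
}

strip_labels_node <- function(node) {
  if (node$leaf) return(new_leaf())
  new_inode(strip_labels_node(node$kids[[1]]), strip_labels_node(node$kids[[2]]))
}

#' Forgetful maps between the four kinds of trees
#'
#' `shape_of()` forgets both labels and order, landing in unordered tree
#' shapes from any kind; `forget_order()` forgets only the child order
#' (ordered cladogram -> cladogram, ordered shape -> shape); `forget_labels()`
#' forgets only the labels (ordered cladogram -> ordered shape, cladogram ->
#' shape).  Forgetting commutes: forgetting order then labels equals
#' forgetting labels then order.
#'
#' @param t an `alpha_tree`.
#' @return An `alpha_tree` of the corresponding kind.
#' @examples
#' shape_of(parse_newick("((1,2),3);"))
#' @export
shape_of <- function(t) {
  stopifnot(inherits(t, "alpha_tree"))
  new_tree(strip_labels_node(t$root), "shape")
}

#' @rdname shape_of
#' @export
forget_order <- function(t) {
  stopifnot(inherits(t, "alpha_tree"))
  kind <- switch(t$kind,
                 ordered_shape = "shape",
                 ordered_cladogram = "cladogram",
                 t$kind)
  new_tree(t$root, kind)
}

#' @rdname shape_of
#' @export
forget_labels <- function(t) {
  stopifnot(inherits(t, "alpha_tree"))
  kind <- switch(t$kind,
                 cladogram = "shape",
                 ordered_cladogram = "ordered_shape",
                 t$kind)
  new_tree(strip_labels_node(t$root), kind)
}

#' Exact tree equality (isomorphism)
#'
#' Compares two trees of the same kind.  Unordered kinds are stored
#' canonically, so this is isomorphism (of shapes) or label-preserving
#' isomorphism (of cladograms); ordered kinds compare as ordered trees.
#'
#' @param t1,t2 `alpha_tree` objects of the same kind.
#' @return `TRUE` or `FALSE`.
#' @export
tree_equal <- function(t1, t2) {
  stopifnot(inherits(t1, "alpha_tree"), inherits(t2, "alpha_tree"))
  t1$kind == t2$kind && write_newick(t1) == write_newick(t2)
}

#' Preimage counts of the forgetful maps
#'
#' The number of preimages of a tree under the three transport maps of the
#' model: a shape with `n` leaves and `k` symmetric branch points is the image
#' of `n!/2^k` cladograms (`map = "pi"`) and of `2^(n-1-k)` ordered shapes
#' (`map = "pi_o_star"`); a cladogram on `n` leaves is the image of `2^(n-1)`
#' ordered cladograms (`map = "pi_o"`).
#'
#' @param target a tree shape (for `"pi"`, `"pi_o_star"`) or a cladogram (for
#'   `"pi_o"`).
#' @param map which forgetful map to invert.
#' @return A positive integer (exact).
#' @examples
#' tt <- shape_of(parse_newick("(((1,2),(3,4)),(((5,6),7),8));"))
#' preimage_count(tt, "pi")        # 8!/2^4 = 2520
#' preimage_count(tt, "pi_o_star") # 2^3 = 8
#' @export
preimage_count <- function(target, map = c("pi", "pi_o", "pi_o_star")) {
  map <- match.arg(map)
  stopifnot(inherits(target, "alpha_tree"))
  n <- target$n
  if (map == "pi_o") {
    if (!kind_is_labeled(target$kind)) {
      stop("map 'pi_o' inverts over a cladogram", call. = FALSE)
    }
    return(ipow(2, n - 1))
  }
  if (kind_is_labeled(target$kind)) {
    stop("maps 'pi' and 'pi_o_star' invert over a tree shape", call. = FALSE)
  }
  k <- symmetric_branch_count(target)
  if (map == "pi") ifactorial(n) / ipow(2, k) else ipow(2, n - 1 - k)
}

#' Join two trees below a new root
#'
#' The root join `t1 * t2` hangs `t1` and `t2` from a fresh root.  For
#' labeled kinds the label sets must be disjoint.  Ordered kinds keep `t1`
#' before `t2`; unordered kinds are re-canonicalized.  The numerical splits of
#' the join are those of the parts plus the new root split.
#'
#' @param t1,t2 `alpha_tree` objects of the same kind.
#' @return An `alpha_tree` of that kind.
#' @examples
#' cat4 <- parse_newick("(((5,6),7),8);")
#' bal4 <- parse_newick("((1,2),(3,4));")
#' write_newick(root_join(bal4, cat4))
#' @export
root_join <- function(t1, t2) {
  stopifnot(inherits(t1, "alpha_tree"), inherits(t2, "alpha_tree"))
  if (t1$kind != t2$kind) stop("root_join requires trees of the same kind", call. = FALSE)
  if (kind_is_labeled(t1$kind)) {
    l1 <- tree_labels(t1); l2 <- tree_labels(t2)
    if (length(intersect(l1, l2))) {
      stop("root_join of cladograms requires disjoint label sets", call. = FALSE)
    }
  }
  new_tree(new_inode(t1$root, t2$root), t1$kind)
}

#' Leaf labels of a tree
#'
#' @param t an `alpha_tree` of a labeled kind.
#' @return Character vector of labels in tree traversal order.
#' @export
tree_labels <- function(t) {
  stopifnot(inherits(t, "alpha_tree"))
  out <- character(0)
  rec <- function(node) {
    if (node$leaf) out[[length(out) + 1L]] <<- node$label
    else { rec(node$kids[[1]]); rec(node$kids[[2]]) }
  }
  rec(t$root)
  out
}

#' Attach labels to a tree shape
#'
#' Labels the leaves of a shape (in its canonical traversal order) with the
#' given labels, producing a cladogram.  Used e.g. to pick a representative
#' cladogram of a shape, or to relabel uniformly at random when sampling.
#'
#' @param shape a `tree_shape` (or `ordered_tree_shape`).
#' @param labels character or integer vector, one label per leaf, distinct.
#' @return A `cladogram` (or `ordered_cladogram`).
#' @export
label_shape <- function(shape, labels = seq_len(n_leaves(shape))) {
  stopifnot(inherits(shape, "alpha_tree"))
  if (kind_is_labeled(shape$kind)) stop("tree is already labeled", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != shape$n || anyDuplicated(labels)) {
    stop("need exactly one distinct label per leaf", call. = FALSE)
  }
  i <- 0L
  rec <- function(node) {
    if (node$leaf) {
      i <<- i + 1L
      return(new_leaf(labels[i]))
    }
    new_inode(rec(node$kids[[1]]), rec(node$kids[[2]]))
  }
  kind <- if (kind_is_ordered(shape$kind)) "ordered_cladogram" else "cladogram"
  new_tree(rec(shape$root), kind)
}
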