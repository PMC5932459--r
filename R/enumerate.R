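# Exhaustive enumeration of shapes and cladograms for small leaf counts, and
# the leaf-insertion machinery shared with the growth process.
#
# A cladogram with l leaves offers 2l-1 attachment points for the next leaf:
# the l pendant arcs, the l-2 internal arcs, and the position above the root.
# All three cases are the same operation "replace the node X below the chosen
# arc (or the root) by a new internal node with children (X, new leaf)", so a
# position is simply a path to a node.

# paths to all nodes, grouped: pendant arcs ordered by numeric leaf label,
# then internal (non-root) arcs in preorder, then the new-root position
collect_positions <- function(root) {
  pend <- list(); pend_lab <- numeric(0)
  internal <- list()
  rec <- function(node, path, is_root) {
    if (node$leaf) {
      if (is_root) return(invisible())  # a lone leaf: only the new-root position
      pend[[length(pend) + 1L]] <<- path
      pend_lab[[length(pend_lab) + 1L]] <<- suppressWarnings(as.numeric(node$label))
      return(invisible())
    }
    if (!is_root) internal[[length(internal) + 1L]] <<- path
    rec(node$kids[[1]], c(path, 1L), FALSE)
    rec(node$kids[[2]], c(path, 2L), FALSE)
  }
  rec(root, integer(0), TRUE)
  if (!anyNA(pend_lab)) pend <- pend[order(pend_lab)]
  c(pend, internal, list(integer(0)))   # last entry: new root
}

# attach a new leaf below the arc leading to the node at `path`
insert_leaf_at <- function(root, path, label) {
  rec <- function(node, depth) {
    if (depth > length(path)) return(new_inode(node, new_leaf(label)))
    i <- path[depth]
    kids <- node$kids
    kids[[i]] <- rec(kids[[i]], depth + 1L)
    list(leaf = FALSE, n = node$n + 1L, kids = kids)
  }
  rec(root, 1L)
}

.fordalpha_cache <- new.env(parent = emptyenv())

#' Enumerate all tree shapes with n leaves
#'
#' Exhaustive, duplicate-free, deterministic-order enumeration; the number of
#' shapes is the Wedderburn-Etherington number of `n` (1, 1, 1, 2, 3, 6, 11,
#' 23, 46, 98 for n = 1..10).
#'
#' @param n leaf count, `1 <= n <= 10`.
#' @return A list of `tree_shape` objects.
#' @examples
#' length(enumerate_shapes(5))  # 3
#' @export
enumerate_shapes <- function(n) {
  stopifnot(length(n) == 1, n == round(n))
  if (n < 1 || n > 10) stop("enumerate_shapes supports 1 <= n <= 10", call. = FALSE)
  key <- paste0("shapes", n)
  if (!is.null(.fordalpha_cache[[key]])) return(.fordalpha_cache[[key]])
  out <- if (n == 1) {
    list(new_tree(new_leaf(), "shape"))
  } else {
    acc <- list()
    for (a in seq_len(n %/% 2)) {
      sa <- enumerate_shapes(a)
      sb <- enumerate_shapes(n - a)
      if (a < n - a) {
        for (x in sa) for (y in sb) {
          acc[[length(acc) + 1L]] <- new_tree(new_inode(x$root, y$root), "shape")
        }
      } else {
        for (i in seq_along(sa)) for (j in i:length(sb)) {
          acc[[length(acc) + 1L]] <-
            new_tree(new_inode(sa[[i]]$root, sb[[j]]$root), "shape")
        }
      }
    }
    acc
  }
  .fordalpha_cache[[key]] <- out
  out
}

#' Enumerate all ordered tree shapes with n leaves
#'
#' All plane (ordered) rooted bifurcating shapes; their number is the Catalan
#' number `C(n-1)` (1, 1, 2, 5, 14, 42, 132, 429 for n = 1..8).
#'
#' @param n leaf count, `1 <= n <= 10`.
#' @return A list of `ordered_tree_shape` objects.
#' @export
enumerate_ordered_shapes <- function(n) {
  stopifnot(length(n) == 1, n == round(n))
  if (n < 1 || n > 10) stop("enumerate_ordered_shapes supports 1 <= n <= 10", call. = FALSE)
  key <- paste0("oshapes", n)
  if (!is.null(.fordalpha_cache[[key]])) return(.fordalpha_cache[[key]])
  out <- if (n == 1) {
    list(new_tree(new_leaf(), "ordered_shape"))
  } else {
    acc <- list()
    for (a in seq_len(n - 1)) {
      for (x in enumerate_ordered_shapes(a)) {
        for (y in enumerate_ordered_shapes(n - a)) {
          acc[[length(acc) + 1L]] <- new_tree(new_inode(x$root, y$root),
                                              "ordered_shape",
                                              canonicalize = FALSE)
        }
      }
    }
    acc
  }
  .fordalpha_cache[[key]] <- out
  out
}

#' Visit every cladogram on leaves 1..n
#'
#' Generates all `(2n-3)!!` cladograms by the unique-construction scheme
#' (insert leaf `m` into each of the `2m-3` attachment points of every
#' cladogram on `1..m-1`), calling `f` once per cladogram.  Each cladogram is
#' produced exactly once.  `enumerate_cladograms()` collects them into a list;
#' the visitor form avoids holding all trees in memory at `n = 8`
#' (135135 trees).
#'
#' @param n leaf count, `1 <= n <= 8`.
#' @param f a function of one argument, the canonical `cladogram`.
#' @return `for_each_cladogram()`: the number of cladograms visited,
#'   invisibly.  `enumerate_cladograms()`: a list of `cladogram` objects.
#' @examples
#' length(enumerate_cladograms(4))  # 15
#' @export
for_each_cladogram <- function(n, f) {
  stopifnot(length(n) == 1, n == round(n), is.function(f))
  if (n < 1 || n > 8) stop("cladogram enumeration supports 1 <= n <= 8", call. = FALSE)
  count <- 0L
  visit <- function(root, m) {
    if (m == n) {
      count <<- count + 1L
      f(new_tree(root, "cladogram"))
      return(invisible())
    }
    for (path in collect_positions(root)) {
      visit(insert_leaf_at(root, path, as.character(m + 1L)), m + 1L)
    }
  }
  visit(new_leaf("1"), 1L)
  invisible(count)
}

#' @rdname for_each_cladogram
#' @export
enumerate_cladograms <- function(n) {
  acc <- vector("list", 0)
  i <- 0L
  expected <- if (n >= 2) idouble_factorial_odd(2 * n - 3) else 1
  acc <- vector("list", expected)
  for_each_cladogram(n, function(t) {
    i <<- i + 1L
    acc[[i]] <<- t
  })
  acc
}
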