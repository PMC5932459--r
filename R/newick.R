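# Newick reading and writing for the package's minimal dialect: strictly
# bifurcating, no branch lengths, no internal labels; tree shapes use empty
# leaf names ("((,),);").  The writer emits unordered trees in canonical child
# order, so write_newick() is a canonical form and parse/write round-trip.

#' Parse a Newick string
#'
#' Reads a rooted bifurcating tree.  `mode` selects the kind of object:
#' cladogram modes require nonempty, distinct leaf labels; shape modes discard
#' any labels; ordered modes keep the child order as written, unordered modes
#' canonicalize it.  Malformed input (non-binary nodes, duplicate labels,
#' stray text) raises an error with the character position.
#'
#' @param text a single Newick string; the trailing `;` is optional.
#' @param mode one of `"cladogram"`, `"shape"`, `"ordered_cladogram"`,
#'   `"ordered_shape"`.
#' @return An `alpha_tree` of the requested kind.
#' @examples
#' parse_newick("((1,2),(3,((4,5),(6,7))));")
#' parse_newick("((,),);", mode = "shape")
#' @export
parse_newick <- function(text, mode = c("cladogram", "shape",
                                        "ordered_cladogram", "ordered_shape")) {
  mode <- match.arg(mode)
  stopifnot(is.character(text), length(text) == 1)
  chars <- strsplit(trimws(text), "")[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  fail <- function(msg) {
    stop(sprintf("Newick parse error at character %d: %s", pos, msg),
         call. = FALSE)
  }
  labeled <- kind_is_labeled(mode)

  parse_node <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      left <- parse_node()
      if (peek() != ",") fail("expected ',' (every internal node must have exactly two children)")
      pos <<- pos + 1L
      right <- parse_node()
      if (peek() == ",") fail("non-binary node: more than two children")
      if (peek() != ")") fail("expected ')'")
      pos <<- pos + 1L
      if (grepl("[^(),;]", peek())) fail("internal node labels are not supported")
      return(new_inode(left, right))
    }
    # leaf: read a (possibly empty) label up to a structural character
    lab <- character(0)
    while (!(peek() %in% c("", "(", ")", ",", ";"))) {
      lab <- c(lab, peek())
      pos <<- pos + 1L
    }
    if (peek() == "(") fail("unexpected '('")
    lab <- paste(lab, collapse = "")
    if (labeled && !nzchar(lab)) fail("cladogram leaves must be labeled")
    new_leaf(if (nzchar(lab)) lab else NA_character_)
  }

  root <- parse_node()
  if (peek() == ";") pos <- pos + 1L
  if (pos <= length(chars)) fail("trailing text after tree")
  if (labeled) {
    labs <- character(0)
    collect <- function(node) {
      if (node$leaf) labs[[length(labs) + 1L]] <<- node$label
      else { collect(node$kids[[1]]); collect(node$kids[[2]]) }
    }
    collect(root)
    if (anyDuplicated(labs)) {
      fail(sprintf("duplicate leaf label '%s'", labs[duplicated(labs)][1]))
    }
  } else {
    root <- strip_labels_node(root)
  }
  new_tree(root, mode)
}

#' Write a tree as Newick
#'
#' Emits the canonical Newick form: unordered kinds in canonical child order,
#' shapes with empty leaf names, trailing semicolon.  `parse_newick()` of the
#' output recovers an equal tree.
#'
#' @param t an `alpha_tree`.
#' @return A single Newick string.
#' @export
write_newick <- function(t) {
  stopifnot(inherits(t, "alpha_tree"))
  rec <- function(node) {
    if (node$leaf) {
      return(if (is.na(node$label)) "" else node$label)
    }
    paste0("(", rec(node$kids[[1]]), ",", rec(node$kids[[2]]), ")")
  }
  paste0(rec(t$root), ";")
}

#' @export
print.alpha_tree <- function(x, ...) {
  cat(sprintf("<%s, %d leaves> %s\n", x$kind, x$n, write_newick(x)))
  invisible(x)
}

#' Convert a cladogram to an ape "phylo" object
#'
#' Convenience bridge to the wider phylogenetics ecosystem (requires the ape
#' package).  Only labeled kinds can be converted.
#'
#' @param t a `cladogram` or `ordered_cladogram`.
#' @return An object of class `phylo`.
#' @export
as_phylo <- function(t) {
  stopifnot(inherits(t, "alpha_tree"))
  if (!kind_is_labeled(t$kind)) {
    stop("only cladograms (labeled trees) convert to phylo", call. = FALSE)
  }
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the ape package is required for as_phylo()", call. = FALSE)
  }
  ape::read.tree(text = write_newick(t))
}
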