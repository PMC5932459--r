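# Shared fixtures and brute-force oracles, all built in code.

# the 8-leaf counterexample cladogram: balanced 4-tree joined with a 4-leaf
# caterpillar; the smallest tree on which the published product formula halves
# the true probability
NWK_TSTAR <- "(((1,2),(3,4)),(((5,6),7),8));"
# the 7-leaf worked example whose split multiset is {(1,1)x3,(2,2),(1,4),(2,5)}
NWK_FIG2 <- "((1,2),(3,((4,5),(6,7))));"
# the 5-leaf shape with splits {(2,3),(1,2),(1,1),(1,1)}
NWK_FIG4_SHAPE <- "((,),((,),));"
NWK_CAT4 <- "(((1,2),3),4);"
NWK_BAL4 <- "((1,2),(3,4));"

t_tilde <- function() parse_newick(NWK_TSTAR)
fig2_tree <- function() parse_newick(NWK_FIG2)
fig4_shape <- function() parse_newick(NWK_FIG4_SHAPE, mode = "shape")

rf <- function(s) parse_alpha_fun(s)

# independent recursive isomorphism test (tries both child matchings)
iso_brute <- function(n1, n2) {
  if (n1$leaf || n2$leaf) return(n1$leaf && n2$leaf)
  (iso_brute(n1$kids[[1]], n2$kids[[1]]) && iso_brute(n1$kids[[2]], n2$kids[[2]])) ||
    (iso_brute(n1$kids[[1]], n2$kids[[2]]) && iso_brute(n1$kids[[2]], n2$kids[[1]]))
}

tree_root <- function(t) t$root

# random topology by recursive random splitting (independent of the package's
# growth process); returns a newick string on labels 1..n in random placement
random_newick <- function(n, labels = sample(n)) {
  build <- function(labs) {
    if (length(labs) == 1) return(as.character(labs))
    m <- if (length(labs) == 2) 1 else sample(length(labs) - 1, 1)
    paste0("(", build(labs[seq_len(m)]), ",", build(labs[-seq_len(m)]), ")")
  }
  paste0(build(labels), ";")
}

# all 2^(n-1) orderings of a cladogram, as ordered cladograms
all_orderings <- function(t) {
  out <- list()
  rec <- function(node) {
    if (node$leaf) return(list(node))
    l <- rec(node$kids[[1]])
    r <- rec(node$kids[[2]])
    acc <- list()
    for (a in l) for (b in r) {
      acc[[length(acc) + 1L]] <- list(leaf = FALSE, n = node$n, kids = list(a, b))
      acc[[length(acc) + 1L]] <- list(leaf = FALSE, n = node$n, kids = list(b, a))
    }
    acc
  }
  roots <- rec(t$root)
  nwk <- function(node) {
    if (node$leaf) return(if (is.na(node$label)) "" else node$label)
    paste0("(", nwk(node$kids[[1]]), ",", nwk(node$kids[[2]]), ")")
  }
  mode <- if (t$kind %in% c("cladogram", "ordered_cladogram")) "ordered_cladogram" else "ordered_shape"
  lapply(roots, function(r) parse_newick(paste0(nwk(r), ";"), mode))
}

# all distinct labelings of a shape with labels 1..n, as canonical newicks
all_labelings <- function(shape) {
  n <- n_leaves(shape)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  unique(vapply(perms(seq_len(n)),
                function(p) write_newick(label_shape(shape, p)),
                character(1)))
}
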