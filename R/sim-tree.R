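#' Simulate a Yule tree
#'
#' Pure-birth tree with a fixed number of tips, standing in for an
#' empirical ortholog phylogeny. Thin, seed-controlled wrapper around
#' [ape::rphylo()] with death rate zero.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param birth_rate speciation rate (1/time, > 0).
#' @param seed RNG seed.
#' @return A rooted binary `phylo` tree with `n_taxa` uniquely labelled
#'   leaves and strictly positive branch lengths.
#' @export
generate_yule_tree <- function(n_taxa, birth_rate = 1, seed = 0L) {
  if (n_taxa < 2) stop_invalid("n_taxa must be >= 2")
  if (birth_rate <= 0) stop_invalid("birth_rate must be > 0")
  tr <- with_seed(split_seed(seed, "yule"),
                  ape::rphylo(n = n_taxa, birth = birth_rate, death = 0))
  tr$tip.label <- sprintf("t%d", seq_len(n_taxa))
  tr
}

#' Read / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()]; writing
#' keeps 10 significant digits so a round trip preserves branch lengths
#' to well below 1e-9.
#'
#' @param path file path.
#' @return `read_newick`: a `phylo`; `write_newick`: the Newick string,
#'   invisibly if `path` is given.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop_invalid("Newick parse error in ", path, ": ",
                                                  conditionMessage(e)))
  if (is.null(tr)) stop_invalid("Newick parse error in ", path)
  if (is.null(tr$edge.length)) stop_invalid("tree has no branch lengths")
  tr
}

#' @param tree a `phylo` object.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 10)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
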