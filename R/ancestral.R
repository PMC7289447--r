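#' Marginal (empirical Bayes) ancestral reconstruction
#'
#' Posterior state distribution at every node of the tree for a single
#' alignment column under a [column_model()]: the inside (pruning)
#' partial likelihood at a node is combined with the outside likelihood
#' of the rest of the tree and normalized.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param column named character vector of leaf states (`-`/`NA` = gap).
#' @param model a [column_model()].
#' @return Matrix of posteriors, one row per node (tips first, in tip
#'   order, then internal nodes in ape numbering), columns named by
#'   state; every row sums to 1.
#' @export
ancestral_marginal <- function(tree, column, model) {
  pp <- postorder_tree(tree)
  column <- column_for_tips(column, pp$tip_label)
  idx <- encode_states(column, model$states)
  N <- length(model$states)
  n_node <- pp$n_node

  if (all(idx == 0L)) {
    warning("all-gap column: posteriors are uniform")
    post <- matrix(1 / N, n_node, N, dimnames = list(NULL, model$states))
    return(post)
  }

  # inside pass (postorder), storing the per-edge message P(t) L_child
  inside <- matrix(1, N, n_node)
  for (i in seq_len(pp$n_tip))
    if (idx[i] > 0) { inside[, i] <- 0; inside[idx[i], i] <- 1 }
  n_edge <- nrow(pp$edge)
  msg <- matrix(0, N, n_edge)  # message from child e up through its edge
  for (e in seq_len(n_edge)) {
    parent <- pp$edge[e, 1]; child <- pp$edge[e, 2]
    P <- sym_chain_P(N, pp$edge_len[e] * model$rate)
    m <- as.vector(P %*% inside[, child])
    m <- m / max(m)
    msg[, e] <- m
    inside[, parent] <- inside[, parent] * m
  }

  # outside pass (preorder = reverse postorder)
  outside <- matrix(1, N, n_node)
  outside[, pp$root] <- 1 / N  # uniform root prior
  edge_of_child <- integer(n_node)
  edge_of_child[pp$edge[, 2]] <- seq_len(n_edge)
  for (e in rev(seq_len(n_edge))) {
    parent <- pp$edge[e, 1]; child <- pp$edge[e, 2]
    sib <- inside[, parent] / pmax(msg[, e], 1e-300)
    # recompute exactly when the division is ill-conditioned
    if (any(msg[, e] < 1e-12)) {
      sib <- rep(1, N)
      for (e2 in which(pp$edge[, 1] == parent)) if (e2 != e) sib <- sib * msg[, e2]
    }
    above <- outside[, parent] * sib
    P <- sym_chain_P(N, pp$edge_len[e] * model$rate)
    o <- as.vector(t(P) %*% above)
    outside[, child] <- o / max(o)
  }

  post <- t(inside * outside)
  post <- post / rowSums(post)
  colnames(post) <- model$states
  post
}
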