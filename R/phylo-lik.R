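# Felsenstein pruning on a fixed tree. Single columns evolve under the
# exchangeable equal-frequency chain normalized to one expected
# substitution per unit time, whose transition probabilities have the
# closed form P_ij(t) = 1/N + (delta_ij - 1/N) exp(-N t/(N-1)); the
# compiled pruning core uses that form directly, so no matrix
# exponential is needed for the independent model.

# postorder bookkeeping reused by every likelihood call on the same tree
postorder_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop_invalid("`tree` must be a phylo object")
  if (is.null(tree$edge.length)) stop_invalid("tree must have branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop_invalid("branch lengths must be finite and >= 0")
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  list(edge = tr$edge, edge_len = tr$edge.length, n_tip = n_tip,
       n_node = n_tip + tr$Nnode, root = n_tip + 1L, tip_label = tr$tip.label)
}

#' Single-column substitution model
#'
#' The "independent" model: a symmetric, equal-frequency chain on a
#' (sub)set of amino-acid states, scaled by a rate multiplier.
#'
#' @param states character vector of allowed states (length >= 2).
#' @param rate positive rate multiplier.
#' @return object of class `column_model`.
#' @export
column_model <- function(states, rate = 1) {
  states <- unique(toupper(states))
  if (length(states) < 2) stop_invalid("column model needs >= 2 states")
  if (!is.finite(rate) || rate <= 0) stop_invalid("rate must be > 0")
  structure(list(states = states, rate = rate), class = "column_model")
}

# map leaf observations (single letters, gap/NA = missing) to 1..N / 0
encode_states <- function(obs, states) {
  obs <- toupper(as.character(obs))
  idx <- match(obs, states)
  idx[is.na(obs) | obs == GAP_CHAR | obs == "X"] <- 0L
  if (anyNA(idx))
    stop_invalid("observed state(s) outside the model state set: ",
                 paste(unique(obs[is.na(idx)]), collapse = " "))
  as.integer(idx)
}

# column: named character vector (names = tip labels) or unnamed in tip order
column_for_tips <- function(column, tip_label) {
  if (!is.null(names(column))) {
    miss <- setdiff(tip_label, names(column))
    if (length(miss)) stop_invalid("column lacks entries for tips: ",
                                   paste(head(miss, 5), collapse = " "))
    column <- column[tip_label]
  } else if (length(column) != length(tip_label)) {
    stop_invalid("column length must equal the number of tips")
  }
  column
}

#' Log-likelihood of one alignment column
#'
#' Felsenstein pruning under a [column_model()]; gaps are treated as
#' missing data (partial-likelihood vector of ones).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param column named character vector mapping tip labels to states
#'   (`-` or `NA` = gap).
#' @param model a [column_model()].
#' @return Log-likelihood (natural log).
#' @export
pruning_loglik_column <- function(tree, column, model) {
  pp <- postorder_tree(tree)
  column <- column_for_tips(column, pp$tip_label)
  idx <- encode_states(column, model$states)
  N <- length(model$states)
  c_prune_loglik(pp$edge, pp$edge_len, pp$n_tip, pp$n_node, idx, 1L, N,
                 matrix(0, 1, 1), matrix(0, 1, 1), numeric(1),
                 rep(1 / N, N), model$rate, pp$root)
}

# fast path used by the fitters: tree already preprocessed, states encoded
prune_sym <- function(pp, idx, N, rate) {
  c_prune_loglik(pp$edge, pp$edge_len, pp$n_tip, pp$n_node, idx, 1L, N,
                 matrix(0, 1, 1), matrix(0, 1, 1), numeric(1),
                 rep(1 / N, N), rate, pp$root)
}

# closed-form symmetric-chain transition matrix (used by tests/reconstruction)
sym_chain_P <- function(N, t) {
  e <- exp(-N * t / (N - 1))
  matrix((1 - e) / N, N, N) + diag(rep(e, N))
}
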