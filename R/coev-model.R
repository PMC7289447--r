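# Pairwise coevolution substitution model: a continuous-time Markov
# chain on the joint state space S = states1 x states2 of two alignment
# columns. Only one position changes per event; any move into a pair
# belonging to the coevolving profile P has rate s, any move into a pair
# outside P has rate d. The chain is reversible with stationary
# distribution pi(state) proportional to (s/d)^[state in P], which makes
# the generator diagonalizable through the standard pi-symmetrization.

#' Construct a coevolution pair model
#'
#' @param states1,states2 residue alphabets of the two positions.
#' @param profile coevolving pairs (2-column character matrix or vector
#'   of 2-letter strings); must lie inside `states1 x states2`.
#' @param s,d rates into profile / non-profile pairs (> 0).
#' @return object of class `coev_model` with the pair-space bookkeeping.
#' @export
coev_model <- function(states1, states2, profile, s, d) {
  if (!is.finite(s) || s <= 0 || !is.finite(d) || d <= 0)
    stop_invalid("s and d must be strictly positive")
  states1 <- unique(toupper(states1)); states2 <- unique(toupper(states2))
  profile <- normalize_profile(profile)
  if (!all(profile[, 1] %in% states1) || !all(profile[, 2] %in% states2))
    stop_invalid("profile must lie inside states1 x states2")
  sp <- pair_space(states1, states2, profile)
  structure(list(states1 = states1, states2 = states2, profile = profile,
                 s = s, d = d, space = sp,
                 pi = setNames(coev_stationary(sp$in_profile, s, d),
                               sp$labels)),
            class = "coev_model")
}

#' Rate matrix and stationary distribution of a coevolution model
#'
#' @param model a [coev_model()].
#' @return list with `Q` (labelled generator, rows summing to zero) and
#'   `pi` (closed-form stationary distribution).
#' @export
coev_rate_matrix <- function(model) {
  sp <- model$space
  n <- sp$n1 * sp$n2
  rate_to <- ifelse(sp$in_profile, model$s, model$d)
  Q <- matrix(0, n, n, dimnames = list(sp$labels, sp$labels))
  for (k in seq_len(n)) Q[k, sp$neighbours[[k]]] <- rate_to[sp$neighbours[[k]]]
  diag(Q) <- -rowSums(Q)
  list(Q = Q, pi = model$pi)
}

# eigendecomposition of the reversible generator via pi-symmetrization:
# S = D^{1/2} Q D^{-1/2} is symmetric, so Q = (D^{-1/2} U) L (U' D^{1/2})
coev_eigen <- function(model) {
  qm <- coev_rate_matrix(model)
  sq <- sqrt(model$pi)
  S <- qm$Q * (sq %o% (1 / sq))
  S <- (S + t(S)) / 2  # remove rounding asymmetry
  es <- eigen(S, symmetric = TRUE)
  list(V = es$vectors / sq, Vinv = t(es$vectors) * rep(sq, each = nrow(S)),
       lambda = es$values, pi = model$pi)
}

# encode a leaf pair observation; gap in either position = missing
encode_pair_states <- function(col1, col2, model) {
  sp <- model$space
  a1 <- toupper(as.character(col1)); a2 <- toupper(as.character(col2))
  gap <- a1 %in% c(GAP_CHAR, "X", NA) | a2 %in% c(GAP_CHAR, "X", NA) |
    is.na(a1) | is.na(a2)
  i1 <- match(a1, model$states1); i2 <- match(a2, model$states2)
  if (any(!gap & (is.na(i1) | is.na(i2))))
    stop_invalid("leaf pair state outside the model state space")
  idx <- i1 + (i2 - 1L) * sp$n1
  idx[gap] <- 0L
  as.integer(idx)
}

#' Log-likelihood of a column pair under the coevolution model
#'
#' Felsenstein pruning on the pair state space, with transition
#' probabilities `expm(Q t)` obtained from the symmetrized
#' eigendecomposition of the reversible generator and the stationary
#' distribution as root prior. A gap in either column makes the leaf
#' missing.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param col1,col2 named character vectors of leaf states.
#' @param model a [coev_model()].
#' @return Log-likelihood.
#' @export
coev_loglik <- function(tree, col1, col2, model) {
  pp <- postorder_tree(tree)
  col1 <- column_for_tips(col1, pp$tip_label)
  col2 <- column_for_tips(col2, pp$tip_label)
  idx <- encode_pair_states(col1, col2, model)
  eg <- coev_eigen(model)
  if (any(!is.finite(eg$lambda)))
    stop("eigendecomposition of the pair generator failed (non-finite values)")
  c_prune_loglik(pp$edge, pp$edge_len, pp$n_tip, pp$n_node, idx, 0L,
                 length(eg$pi), eg$V, eg$Vinv, eg$lambda, eg$pi, 1, pp$root)
}
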