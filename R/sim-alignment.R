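# Sequence simulation on a fixed phylogeny.
#
# Independent columns evolve under the exchangeable equal-frequency chain
# normalized to one expected substitution per unit branch length; state
# propagation along a branch uses the exact closed-form transition
# probabilities (jump/no-jump coupling), so there is no discretization.
# Coevolving column pairs evolve as one Markov chain on the pair state
# space via exact Gillespie simulation.

# exact draw of child states given parent states for the symmetric chain:
# with prob exp(-N r t/(N-1)) the state is copied, otherwise resampled
# uniformly over all N states (this coupling reproduces P_ij(t) exactly)
sym_chain_evolve <- function(parent_states, t, rates, n_states) {
  e <- exp(-n_states * rates * t / (n_states - 1))
  jump <- stats::runif(length(parent_states)) >= e
  out <- parent_states
  n_j <- sum(jump)
  if (n_j > 0) out[jump] <- sample.int(n_states, n_j, replace = TRUE)
  out
}

#' Simulate an alignment under independent column evolution
#'
#' Every column evolves independently under the 20-state symmetric
#' (equal-exchangeability, uniform-frequency) substitution chain with its
#' own rate multiplier; the root state is drawn from the uniform
#' equilibrium. This is the null generator used to calibrate the
#' coevolution test.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param n_cols number of columns.
#' @param col_rates per-column rate multipliers (recycled if length 1);
#'   default 0.05, a strongly conserved interface position.
#' @param seed RNG seed.
#' @return An [aa_alignment()] with one row per leaf.
#' @export
simulate_alignment_independent <- function(tree, n_cols, col_rates = 0.05,
                                           seed = 0L) {
  if (!inherits(tree, "phylo") || length(tree$tip.label) < 2)
    stop_invalid("`tree` must be a phylo with >= 2 tips")
  n_cols <- as.integer(n_cols)
  if (length(col_rates) == 1L) col_rates <- rep(col_rates, n_cols)
  if (length(col_rates) != n_cols) stop_invalid("col_rates length must equal n_cols")
  if (any(col_rates <= 0)) stop_invalid("col_rates must be positive")

  N <- length(AA_ALPHABET)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  n_tip <- length(tr$tip.label)
  n_nodes <- n_tip + tr$Nnode
  root <- n_tip + 1L

  states <- with_seed(split_seed(seed, "msa_indep"), {
    st <- matrix(NA_integer_, n_nodes, n_cols)
    st[root, ] <- sample.int(N, n_cols, replace = TRUE)
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      st[ch, ] <- sym_chain_evolve(st[p, ], tr$edge.length[e], col_rates, N)
    }
    st
  })

  m <- matrix(AA_ALPHABET[states[seq_len(n_tip), , drop = FALSE]],
              n_tip, n_cols, dimnames = list(tr$tip.label, NULL))
  aa_alignment(m)
}

# normalize a coevolving profile to a 2-column character matrix
normalize_profile <- function(profile) {
  if (is.character(profile) && !is.matrix(profile)) {
    if (any(nchar(profile) != 2)) stop_invalid("profile strings must be 2 letters")
    profile <- cbind(substr(profile, 1, 1), substr(profile, 2, 2))
  }
  if (!is.matrix(profile) || ncol(profile) != 2 || nrow(profile) < 1)
    stop_invalid("profile must be a non-empty set of residue pairs")
  profile[] <- toupper(profile)
  if (!all(profile %in% AA_ALPHABET)) stop_invalid("profile contains non-amino-acid letters")
  unique(profile)
}

# neighbour bookkeeping for the pair chain: single-position moves only
pair_space <- function(states1, states2, profile) {
  n1 <- length(states1); n2 <- length(states2)
  labels <- as.vector(outer(states1, states2, paste0))  # index k = i + (j-1) n1
  in_p <- labels %in% paste0(profile[, 1], profile[, 2])
  nbr <- vector("list", n1 * n2)
  for (j in seq_len(n2)) for (i in seq_len(n1)) {
    k <- i + (j - 1L) * n1
    a <- setdiff(seq_len(n1), i) + (j - 1L) * n1     # change position 1
    b <- i + (setdiff(seq_len(n2), j) - 1L) * n1     # change position 2
    nbr[[k]] <- c(a, b)
  }
  list(n1 = n1, n2 = n2, labels = labels, in_profile = in_p, neighbours = nbr)
}

# stationary distribution of the pair chain: pi proportional to (s/d)^[in P]
coev_stationary <- function(in_profile, s, d) {
  w <- ifelse(in_profile, s / d, 1)
  w / sum(w)
}

#' Simulate coevolving column pairs on a phylogeny
#'
#' Each column pair evolves as a single continuous-time Markov chain on
#' the pair state space `states1 x states2`: only one position changes at
#' a time, with rate `s` into any pair belonging to the coevolving
#' profile and rate `d` into any pair outside it. Branches are simulated
#' exactly with the Gillespie algorithm; the root state is drawn from the
#' stationary distribution `pi ~ (s/d)^[state in profile]`.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param profile coevolving pairs: character matrix with two columns, or
#'   a vector of two-letter strings such as `c("DR", "EK")`.
#' @param s,d rates into profile / non-profile pairs (> 0).
#' @param n_pairs number of column pairs to simulate; pair `p` occupies
#'   alignment columns `2p - 1` and `2p`.
#' @param seed RNG seed.
#' @param states1,states2 residue alphabets of the two positions; default
#'   the residues appearing in the profile.
#' @return An [aa_alignment()] with `2 * n_pairs` columns.
#' @export
simulate_alignment_coev <- function(tree, profile, s, d, n_pairs, seed = 0L,
                                    states1 = NULL, states2 = NULL) {
  if (!is.finite(s) || s <= 0 || !is.finite(d) || d <= 0)
    stop_invalid("s and d must be strictly positive")
  profile <- normalize_profile(profile)
  if (is.null(states1)) states1 <- sort(unique(profile[, 1]))
  if (is.null(states2)) states2 <- sort(unique(profile[, 2]))
  if (!all(profile[, 1] %in% states1) || !all(profile[, 2] %in% states2))
    stop_invalid("profile must lie inside states1 x states2")

  sp <- pair_space(states1, states2, profile)
  n_states <- sp$n1 * sp$n2
  rate_to <- ifelse(sp$in_profile, s, d)   # rate of any move INTO state k
  total_rate <- vapply(sp$neighbours, function(nb) sum(rate_to[nb]), numeric(1))
  pi0 <- coev_stationary(sp$in_profile, s, d)

  tr <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tr$tip.label)
  root <- n_tip + 1L
  n_nodes <- n_tip + tr$Nnode
  n_pairs <- as.integer(n_pairs)

  gillespie <- function(state, t) {
    repeat {
      r <- total_rate[state]
      if (r <= 0) return(state)
      t <- t - stats::rexp(1, r)
      if (t < 0) return(state)
      nb <- sp$neighbours[[state]]
      state <- nb[sample.int(length(nb), 1L, prob = rate_to[nb])]
    }
  }

  states <- with_seed(split_seed(seed, "msa_coev"), {
    st <- matrix(NA_integer_, n_nodes, max(n_pairs, 1L))
    if (n_pairs > 0) {
      st[root, ] <- sample.int(n_states, n_pairs, replace = TRUE, prob = pi0)
      for (e in seq_len(nrow(tr$edge))) {
        p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
        for (k in seq_len(n_pairs))
          st[ch, k] <- gillespie(st[p, k], tr$edge.length[e])
      }
    }
    st
  })

  m <- matrix(GAP_CHAR, n_tip, 2L * n_pairs, dimnames = list(tr$tip.label, NULL))
  if (n_pairs > 0) {
    for (k in seq_len(n_pairs)) {
      lab <- sp$labels[states[seq_len(n_tip), k]]
      m[, 2L * k - 1L] <- substr(lab, 1, 1)
      m[, 2L * k] <- substr(lab, 2, 2)
    }
  }
  aa_alignment(m)
}
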