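# Maximum-likelihood fits of the independent and coevolution models for
# one column pair, on the tree with fixed branch lengths. Both models
# carry two free parameters (one rate per column vs (s, d)), so
# dAIC = 2 (logL_coev - logL_independent). Optimization is on log
# parameters, bounded, with dispersed multi-starts.

RATE_LOG_BOUNDS <- c(-9, 7)  # rate multipliers from ~1e-4 to ~1100

fit_result <- function(logL, parameters, k, convergence = TRUE) {
  structure(list(logL = logL, parameters = parameters, k = k,
                 AIC = 2 * k - 2 * logL, converged = convergence),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: logL = %.6f, AIC = %.6f, k = %d%s\n  parameters: %s\n",
              x$logL, x$AIC, x$k, if (x$converged) "" else " [NOT CONVERGED]",
              paste(names(x$parameters), signif(x$parameters, 6),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

# shared preparation: tips with both columns observed, per-column states
prep_pair <- function(tree, col1, col2) {
  pp <- postorder_tree(tree)
  col1 <- toupper(column_for_tips(col1, pp$tip_label))
  col2 <- toupper(column_for_tips(col2, pp$tip_label))
  gap1 <- col1 %in% c(GAP_CHAR, "X") | is.na(col1)
  gap2 <- col2 %in% c(GAP_CHAR, "X") | is.na(col2)
  n_ungapped <- sum(!gap1 & !gap2)
  if (n_ungapped < 4)
    stop_invalid("need >= 4 leaves ungapped in both columns (have ", n_ungapped, ")")
  list(pp = pp, col1 = col1, col2 = col2, gap1 = gap1, gap2 = gap2,
       n_ungapped = n_ungapped)
}

#' Fit the independent model to a column pair
#'
#' Maximizes the pruning likelihood over one symmetric-chain rate per
#' column (k = 2 free parameters). Each column's state space is
#' restricted to its observed residues; a constant column contributes
#' log-likelihood 0 with an indeterminate rate.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param col1,col2 named character vectors of leaf states.
#' @return A `fit_result` with parameters `rate1`, `rate2`.
#' @export
fit_independent_pair <- function(tree, col1, col2) {
  pr <- prep_pair(tree, col1, col2)
  fit1 <- fit_column_rate(pr$pp, pr$col1)
  fit2 <- fit_column_rate(pr$pp, pr$col2)
  fit_result(fit1$logL + fit2$logL,
             c(rate1 = fit1$rate, rate2 = fit2$rate), k = 2L,
             convergence = fit1$ok && fit2$ok)
}

fit_column_rate <- function(pp, col) {
  obs <- col[!(col %in% c(GAP_CHAR, "X") | is.na(col))]
  states <- sort(unique(obs))
  if (length(states) < 2) return(list(logL = 0, rate = NA_real_, ok = TRUE))
  idx <- encode_states(col, states)
  N <- length(states)
  f <- function(lr) -prune_sym(pp, idx, N, exp(lr))
  op <- stats::optimize(f, interval = RATE_LOG_BOUNDS, tol = 1e-8)
  # guard against a boundary/local issue with a coarse grid refinement
  grid <- seq(RATE_LOG_BOUNDS[1], RATE_LOG_BOUNDS[2], length.out = 25)
  gv <- vapply(grid, f, numeric(1))
  if (min(gv) < op$objective - 1e-9) {
    i <- which.min(gv)
    op2 <- stats::optimize(f, interval = grid[c(max(1, i - 1), min(length(grid), i + 1))],
                           tol = 1e-8)
    if (op2$objective < op$objective) op <- op2
  }
  list(logL = -op$objective, rate = exp(op$minimum), ok = TRUE)
}

# coevolving profile observed in the data: unique co-occurring pairs
observed_profile <- function(col1, col2) {
  keep <- !(col1 %in% c(GAP_CHAR, "X") | is.na(col1) |
              col2 %in% c(GAP_CHAR, "X") | is.na(col2))
  unique(cbind(col1[keep], col2[keep]))
}

#' Fit the coevolution model to a column pair
#'
#' Maximizes the pair-chain likelihood over `(s, d)` with the profile
#' fixed to the residue pairs observed at the leaves and the state space
#' restricted to the observed residues of each column (k = 2 free
#' parameters). Bounded quasi-Newton optimization on `(log s, log d)`
#' from five dispersed starts; non-convergence of all starts is flagged
#' on the result rather than silently ignored.
#'
#' @inheritParams fit_independent_pair
#' @param profile optional coevolving profile; default the observed
#'   co-occurring pairs.
#' @return A `fit_result` with parameters `s` and `d`.
#' @export
fit_coev_pair <- function(tree, col1, col2, profile = NULL) {
  pr <- prep_pair(tree, col1, col2)
  obs1 <- sort(unique(pr$col1[!pr$gap1])); obs2 <- sort(unique(pr$col2[!pr$gap2]))
  if (is.null(profile)) {
    profile <- observed_profile(pr$col1, pr$col2)
  } else {
    # a supplied profile is clipped to the observed state space
    profile <- normalize_profile(profile)
    profile <- profile[profile[, 1] %in% obs1 & profile[, 2] %in% obs2, ,
                       drop = FALSE]
    if (!nrow(profile))
      stop_invalid("supplied profile has no pairs inside the observed state space")
  }
  profile <- normalize_profile(profile)

  # model pieces that do not depend on (s, d)
  base <- coev_model(obs1, obs2, profile, 1, 1)
  sp <- base$space
  idx <- encode_pair_states(pr$col1, pr$col2, base)
  n <- sp$n1 * sp$n2
  # flat index pairs of the allowed (single-position) moves, built once
  from_k <- rep(seq_len(n), lengths(sp$neighbours))
  to_k <- unlist(sp$neighbours)
  q_idx <- cbind(from_k, to_k)

  nll <- function(par) {
    s <- exp(par[1]); d <- exp(par[2])
    pi0 <- coev_stationary(sp$in_profile, s, d)
    Q <- matrix(0, n, n)
    Q[q_idx] <- ifelse(sp$in_profile[to_k], s, d)
    diag(Q) <- -rowSums(Q)
    sq <- sqrt(pi0)
    S <- Q * (sq %o% (1 / sq))
    es <- eigen((S + t(S)) / 2, symmetric = TRUE)
    if (any(!is.finite(es$values))) return(1e10)
    V <- es$vectors / sq
    Vinv <- t(es$vectors) * rep(sq, each = n)
    ll <- c_prune_loglik(pr$pp$edge, pr$pp$edge_len, pr$pp$n_tip, pr$pp$n_node,
                         idx, 0L, n, V, Vinv, es$values, pi0, 1, pr$pp$root)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # coarse global grid over (log s, log d) seeds one bounded quasi-Newton
  # refinement; a second dispersed start guards against local optima
  grid <- as.matrix(expand.grid(ls = c(-4, -2.5, -1, 0.5, 2),
                                ld = c(-4, -2.5, -1, 0.5, 2)))
  gv <- apply(grid, 1, nll)
  ord <- order(gv)
  starts <- list(grid[ord[1], ], grid[ord[2], ])
  best <- NULL; any_conv <- FALSE
  for (st in starts) {
    op <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B",
                   lower = RATE_LOG_BOUNDS[1], upper = RATE_LOG_BOUNDS[2],
                   control = list(maxit = 300, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (op$convergence == 0) any_conv <- TRUE
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) stop("coevolution fit failed from every start")
  par <- unname(best$par)
  fit_result(-best$value, c(s = exp(par[1]), d = exp(par[2])),
             k = 2L, convergence = any_conv)
}

#' AIC difference between independent and coevolution fits
#'
#' `dAIC = AIC(independent) - AIC(coevolution)`; large positive values
#' favour coevolution.
#'
#' @param ind,coev `fit_result` objects for the same column pair.
#' @return Numeric dAIC.
#' @export
delta_aic <- function(ind, coev) {
  stopifnot(inherits(ind, "fit_result"), inherits(coev, "fit_result"))
  ind$AIC - coev$AIC
}
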