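tree4 <- ape::read.tree(text = "((A:0.3,B:0.7):0.2,(C:0.5,D:0.1):0.4);")

# closed-form symmetric-chain transition matrix for the enumeration oracle
Pmat <- function(N, t) {
  e <- exp(-N * t / (N - 1))
  matrix((1 - e) / N, N, N) + diag(rep(e, N))
}

test_that("pruning matches exhaustive enumeration over internal states", {
  states <- c("A", "C", "D", "E")
  cm <- column_model(states, rate = 0.8)
  N <- 4
  P <- function(t) Pmat(N, 0.8 * t)
  brute <- function(obs) {
    tot <- 0
    for (r in 1:N) for (u in 1:N) for (v in 1:N)
      tot <- tot + (1 / N) * P(0.2)[r, u] * P(0.4)[r, v] *
        P(0.3)[u, obs[1]] * P(0.7)[u, obs[2]] *
        P(0.5)[v, obs[3]] * P(0.1)[v, obs[4]]
    log(tot)
  }
  set.seed(11)
  for (i in 1:8) {
    obs <- sample(1:4, 4, replace = TRUE)
    col <- setNames(states[obs], c("A", "B", "C", "D"))
    expect_equal(pruning_loglik_column(tree4, col, cm), brute(obs),
                 tolerance = 1e-10)
  }
  # gaps are missing data: enumeration with the gapped tip marginalized
  colg <- c(A = "A", B = "-", C = "C", D = "D")
  brute_gap <- log(sum(vapply(1:N, function(b)
    exp(brute(c(1, b, 2, 3))), numeric(1))))
  expect_equal(pruning_loglik_column(tree4, colg, cm), brute_gap,
               tolerance = 1e-10)
})

test_that("degenerate pruning cases follow the chain exactly", {
  tr0 <- ape::read.tree(text = "(A:0,B:0);")
  cm <- column_model(c("D", "N", "S"), 1)
  expect_equal(pruning_loglik_column(tr0, c(A = "D", B = "D"), cm), log(1 / 3))
  expect_equal(pruning_loglik_column(tr0, c(A = "D", B = "N"), cm), -Inf)
  expect_error(pruning_loglik_column(tr0, c(A = "W", B = "D"), cm),
               "outside the model state set")
})

test_that("likelihood over all possible observations sums to one", {
  tr3 <- ape::read.tree(text = "((A:0.4,B:0.9):0.3,C:0.6);")
  cm <- column_model(c("D", "N", "S"), 0.7)
  tot <- 0
  for (a in c("D", "N", "S")) for (b in c("D", "N", "S")) for (c3 in c("D", "N", "S"))
    tot <- tot + exp(pruning_loglik_column(tr3, c(A = a, B = b, C = c3), cm))
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("transition matrices are stochastic for all tested times", {
  for (t in c(1e-4, 0.01, 0.3, 2, 50)) {
    expect_lt(max(abs(rowSums(Pmat(20, t)) - 1)), 1e-10)
    m <- coev_model(c("D", "N"), c("R", "K", "T"), c("DR", "NK"), s = 1.7, d = 0.2)
    eg <- coevin:::coev_eigen(m)
    P <- eg$V %*% diag(exp(eg$lambda * t)) %*% eg$Vinv
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P > -1e-12))
  }
})

test_that("coevolution generator has the closed-form stationary law", {
  m <- coev_model(c("D", "N", "S", "G"), c("R", "K", "T", "Q"),
                  c("DR", "NK", "ST", "GQ"), s = 2, d = 1)
  qm <- coev_rate_matrix(m)
  expect_lt(max(abs(rowSums(qm$Q))), 1e-12)
  # pi Q = 0 and profile/non-profile ratio s/d = 2
  expect_lt(max(abs(qm$pi %*% qm$Q)), 1e-12)
  expect_equal(unname(qm$pi[match("DR", colnames(qm$Q))] /
                        qm$pi[match("DK", colnames(qm$Q))]), 2)
  # cross-check against a null-space solve of the generator
  ns <- eigen(t(qm$Q))
  v <- Re(ns$vectors[, which.min(abs(ns$values))])
  v <- v / sum(v)
  expect_equal(unname(v), unname(qm$pi), tolerance = 1e-9)

  uni <- coev_model(c("D", "N"), c("R", "K"), c("DR"), s = 1, d = 1)
  expect_true(all(abs(coev_rate_matrix(uni)$pi - 0.25) < 1e-12))

  expect_error(coev_model(c("D"), c("R"), c("DR"), s = 0, d = 1), "positive")
})

test_that("pair likelihood factorizes when s = d and in the full-profile case", {
  tr <- generate_yule_tree(16, 1, seed = 5)
  aln <- simulate_alignment_coev(tr, c("DR", "NK", "ST"), s = 0.2, d = 0.2,
                                 n_pairs = 3, seed = 9)
  m <- unclass(aln)
  s1 <- c("D", "N", "S"); s2 <- c("R", "K", "T")
  for (k in 1:3) {
    c1 <- setNames(m[, 2 * k - 1], rownames(m))
    c2 <- setNames(m[, 2 * k], rownames(m))
    # s = d: product of two symmetric chains with matched rates (N-1) v
    v <- 0.2
    mm <- coev_model(s1, s2, c("DR", "NK", "ST"), s = v, d = v)
    prod_ll <- pruning_loglik_column(tr, c1, column_model(s1, 2 * v)) +
      pruning_loglik_column(tr, c2, column_model(s2, 2 * v))
    expect_equal(coev_loglik(tr, c1, c2, mm), prod_ll, tolerance = 1e-8)
    # full profile P = S: only s matters, same factorization at rate s
    full <- coev_model(s1, s2, as.vector(outer(s1, s2, paste0)), s = 0.35, d = 7)
    prod_s <- pruning_loglik_column(tr, c1, column_model(s1, 2 * 0.35)) +
      pruning_loglik_column(tr, c2, column_model(s2, 2 * 0.35))
    expect_equal(coev_loglik(tr, c1, c2, full), prod_s, tolerance = 1e-8)
    expect_lte(coev_loglik(tr, c1, c2, mm), 0)
  }
})

test_that("pair likelihood reaches the stationarity limit on long branches", {
  tr2 <- ape::read.tree(text = "(A:400,B:400);")
  m <- coev_model(c("D", "N"), c("R", "K"), c("DR", "NK"), s = 1, d = 0.25)
  ll <- coev_loglik(tr2, c(A = "D", B = "N"), c(A = "R", B = "K"), m)
  pi0 <- coev_rate_matrix(m)$pi
  expect_equal(ll, log(pi0["DR"]) + log(pi0["NK"]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("model fits keep the AIC bookkeeping exact", {
  tr <- generate_yule_tree(16, 1, seed = 8)
  aln <- simulate_alignment_independent(tr, 2, 0.3, seed = 3)
  m <- unclass(aln)
  c1 <- setNames(m[, 1], rownames(m)); c2 <- setNames(m[, 2], rownames(m))
  ind <- fit_independent_pair(tr, c1, c2)
  cv <- fit_coev_pair(tr, c1, c2)
  expect_equal(ind$AIC, 2 * 2 - 2 * ind$logL, tolerance = 1e-9)
  expect_equal(cv$AIC, 2 * 2 - 2 * cv$logL, tolerance = 1e-9)
  expect_equal(delta_aic(ind, cv), ind$AIC - cv$AIC)
  expect_equal(delta_aic(ind, cv), 2 * (cv$logL - ind$logL), tolerance = 1e-9)

  f1 <- structure(list(logL = -45, parameters = c(a = 1), k = 2, AIC = 100),
                  class = "fit_result")
  f2 <- structure(list(logL = -43, parameters = c(a = 1), k = 2, AIC = 90),
                  class = "fit_result")
  expect_equal(delta_aic(f1, f2), 10)
  expect_error(fit_independent_pair(tr, c1[1:3], c2[1:3]), "tips|leaves|length")
})

test_that("the coevolution optimum dominates the matched shared-rate point", {
  # numerical nesting check: the fitted coevolution likelihood can never be
  # below the s = d point matched to a shared-rate independent model
  tr <- generate_yule_tree(32, 1, seed = 13)
  aln <- simulate_alignment_coev(tr, c("DR", "NK"), s = 0.15, d = 0.15,
                                 n_pairs = 4, seed = 2)
  m <- unclass(aln)
  for (k in 1:4) {
    c1 <- setNames(m[, 2 * k - 1], rownames(m))
    c2 <- setNames(m[, 2 * k], rownames(m))
    cv <- fit_coev_pair(tr, c1, c2)
    obs1 <- sort(unique(c1)); obs2 <- sort(unique(c2))
    if (length(obs1) < 2 || length(obs2) < 2) next
    prof <- coevin:::observed_profile(c1, c2)
    shared <- coev_loglik(tr, c1, c2, coev_model(obs1, obs2, prof, 0.15, 0.15))
    expect_gte(cv$logL, shared - 1e-6)
  }
})

test_that("rate parameters are recovered from synthetic data", {
  tr <- generate_yule_tree(64, 1, seed = 2)
  prof <- c("DR", "NK", "ST", "EQ", "GA", "LV")
  # under s = d (independent-equivalent data) the fitted ratio is near 1
  r_eq <- vapply(1:10, function(r) {
    a <- simulate_alignment_coev(tr, prof, s = 0.15, d = 0.15, n_pairs = 1,
                                 seed = 40 + r)
    m <- unclass(a)
    cv <- fit_coev_pair(tr, setNames(m[, 1], rownames(m)),
                        setNames(m[, 2], rownames(m)), profile = prof)
    unname(cv$parameters["s"] / cv$parameters["d"])
  }, numeric(1))
  expect_gt(median(r_eq), 0.7)
  expect_lt(median(r_eq), 1.4)
})
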