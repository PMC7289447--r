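test_that("Yule trees have the requested shape and are seed-deterministic", {
  t2 <- generate_yule_tree(2, 1, seed = 7)
  expect_equal(length(t2$tip.label), 2L)
  expect_equal(t2$Nnode, 1L)

  t64 <- generate_yule_tree(64, 1, seed = 1)
  expect_equal(length(t64$tip.label), 64L)
  expect_equal(t64$Nnode, 63L)  # binary rooted tree identity
  expect_true(all(t64$edge.length > 0))
  expect_false(anyDuplicated(t64$tip.label) > 0)

  expect_identical(write_newick(generate_yule_tree(8, 1, seed = 3)),
                   write_newick(generate_yule_tree(8, 1, seed = 3)))
  expect_error(generate_yule_tree(1, 1, 0), "n_taxa")
})

test_that("Newick round trip preserves topology and branch lengths", {
  tr <- read_newick(textConnection_path <- {
    f <- tempfile(); writeLines("(A:1,B:1);", f); f
  })
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(tr$edge.length, c(1, 1))

  t64 <- generate_yule_tree(64, 1, seed = 4)
  f <- tempfile(fileext = ".nwk")
  write_newick(t64, f)
  t64b <- read_newick(f)
  # the weighted cophenetic matrix pins down topology and branch lengths
  c1 <- ape::cophenetic.phylo(t64)
  c2 <- ape::cophenetic.phylo(t64b)[rownames(c1), colnames(c1)]
  expect_lt(max(abs(c1 - c2)), 1e-8)
  expect_equal(sort(t64b$edge.length), sort(t64$edge.length), tolerance = 1e-9)
})

test_that("independent simulator: no time means no change; determinism", {
  tr0 <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  aln <- simulate_alignment_independent(tr0, 30, 0.5, seed = 1)
  m <- unclass(aln)
  expect_true(all(apply(m, 2, function(z) length(unique(z))) == 1))

  tr <- generate_yule_tree(8, 1, seed = 2)
  a1 <- simulate_alignment_independent(tr, 25, 0.1, seed = 9)
  a2 <- simulate_alignment_independent(tr, 25, 0.1, seed = 9)
  expect_identical(unclass(a1), unclass(a2))
  expect_error(simulate_alignment_independent(tr, 4, c(1, 2), seed = 0),
               "col_rates")
})

test_that("independent simulator reaches the uniform equilibrium", {
  # star tree with very long branches: leaf states are i.i.d. uniform
  star <- ape::read.tree(text = "(A:60,B:60,C:60,D:60,E:60,F:60,G:60,H:60);")
  aln <- simulate_alignment_independent(star, 2000, 1, seed = 5)
  counts <- table(factor(unclass(aln), levels = AAS))
  n <- sum(counts)
  se <- sqrt(n * (1 / 20) * (19 / 20))
  expect_true(all(abs(counts - n / 20) < 3 * se + 3))
})

test_that("coevolving simulator matches its stationary distribution", {
  star <- ape::read.tree(text = paste0("(", paste0("t", 1:40, ":80",
                                                   collapse = ","), ");"))
  prof <- c("DR", "NK", "ST")
  # s = d: uniform over the 9-cell pair space (chi-squared GoF)
  a_eq <- simulate_alignment_coev(star, prof, s = 0.3, d = 0.3, n_pairs = 60,
                                  seed = 3)
  m <- unclass(a_eq)
  lab <- paste0(m[, seq(1, 119, 2)], m[, seq(2, 120, 2)])
  tab <- table(factor(lab, levels = as.vector(outer(c("D","N","S"), c("R","K","T"),
                                                    paste0))))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)

  # s = 10 d: closed-form profile mass |P| rho / (|P| rho + |S \ P|)
  a10 <- simulate_alignment_coev(star, prof, s = 0.5, d = 0.05, n_pairs = 60,
                                 seed = 4)
  m10 <- unclass(a10)
  lab10 <- paste0(m10[, seq(1, 119, 2)], m10[, seq(2, 120, 2)])
  frac <- mean(lab10 %in% prof)
  p_exp <- 3 * 10 / (3 * 10 + 6)
  se <- sqrt(p_exp * (1 - p_exp) / length(lab10))
  expect_lt(abs(frac - p_exp), 3 * se)

  # degenerate size and argument validation
  a0 <- simulate_alignment_coev(star, prof, 1, 1, n_pairs = 0, seed = 1)
  expect_equal(ncol(a0), 0L)
  expect_equal(nrow(a0), 40L)
  expect_error(simulate_alignment_coev(star, prof, -1, 1, 1), "positive")
})

test_that("simulation_config validates its invariants", {
  cfg <- simulation_config(seed = 1)
  expect_s3_class(cfg, "sim_config")
  expect_error(simulation_config(bias_factor = 1), "bias_factor")
  expect_error(simulation_config(hill_width = 0), "hill_width")
  expect_error(simulation_config(n_taxa = 1), "n_taxa")
  expect_error(simulation_config(coev_d = -0.1), "coev_d")
})

test_that("toy complexes plant their ground truth exactly", {
  tc <- generate_toy_complex(8, seed = 4)
  expect_equal(nrow(tc$truth$planted_ion_pairs), 1L)
  expect_equal(tc$truth$planted_ion_pairs$dist, 0.45, tolerance = 1e-12)
  expect_equal(tc$truth$planted_hbonds$dist, 0.30, tolerance = 1e-12)
  expect_equal(tc$truth$planted_hbonds$angle, 10)
  expect_gt(nrow(tc$truth$planted_contacts), 0)

  far <- generate_toy_complex(8, seed = 4, separation = 10)
  expect_equal(nrow(far$truth$planted_contacts), 0L)
  expect_equal(nrow(far$truth$planted_ion_pairs), 0L)
  expect_equal(nrow(far$truth$planted_hbonds), 0L)
  expect_error(generate_toy_complex(1), "n_residues_per_chain")
})
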