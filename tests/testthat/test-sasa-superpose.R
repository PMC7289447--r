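test_that("SASA matches the analytic sphere and additivity limits", {
  one <- structure3d(atom_row("A", 1, "GLY", "CA", "C", 0, 0, 0))
  a <- shrake_rupley_sasa(one)
  expect_equal(a, 4 * pi * 0.31^2, tolerance = 0.01)

  two_far <- structure3d(rbind(atom_row("A", 1, "GLY", "CA", "C", 0, 0, 0),
                               atom_row("A", 2, "GLY", "CA", "C", 10, 0, 0)))
  expect_equal(sum(shrake_rupley_sasa(two_far)), 2 * 4 * pi * 0.31^2,
               tolerance = 0.01)

  # atom caged by a tight shell is fully buried
  dirs <- sphere_dirs <- {
    k <- 1:40 - 0.5
    phi <- acos(1 - 2 * k / 40); th <- pi * (1 + sqrt(5)) * k
    cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  }
  shell <- do.call(rbind, lapply(seq_len(nrow(dirs)), function(i)
    atom_row("A", i + 1, "GLY", "CA", "C",
             0.25 * dirs[i, 1], 0.25 * dirs[i, 2], 0.25 * dirs[i, 3])))
  caged <- structure3d(rbind(atom_row("A", 1, "GLY", "CA", "C", 0, 0, 0), shell))
  expect_lt(shrake_rupley_sasa(caged)[1], 1e-6)

  expect_warning(shrake_rupley_sasa(
    structure3d(atom_row("A", 1, "UNK", "X1", "Q", 0, 0, 0))), "unknown element")
})

test_that("SASA total is invariant under rigid-body motion", {
  tc <- generate_toy_complex(5, seed = 7)
  s <- tc$structure
  a0 <- shrake_rupley_sasa(s, n_points = 480)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(s$atoms[c("x", "y", "z")]) %*% R
  s2 <- s
  s2$atoms$x <- xyz[, 1] + 2; s2$atoms$y <- xyz[, 2] - 1; s2$atoms$z <- xyz[, 3]
  a1 <- shrake_rupley_sasa(s2, n_points = 480)
  expect_lt(abs(sum(a0) - sum(a1)), 1e-6)
})

test_that("buried hydrophobic area behaves like an occlusion measure", {
  tc_far <- generate_toy_complex(6, seed = 1, separation = 10)
  expect_lt(abs(buried_hydrophobic_area(tc_far$structure, "A", "B")), 1e-9)

  # planted Leu-Leu stack across chains
  stack <- structure3d(rbind(
    atom_row("A", 1, "LEU", "CA", "C", 0, 0, 0),
    atom_row("A", 1, "LEU", "CB", "C", 0.15, 0, 0),
    atom_row("B", 1, "LEU", "CA", "C", 0.15, 0.35, 0),
    atom_row("B", 1, "LEU", "CB", "C", 0, 0.35, 0)))
  bur <- buried_hydrophobic_area(stack, "A", "B")
  expect_gt(bur, 0)
  # equals the direct SASA difference computed with the naive oracle
  a <- stack$atoms
  alone <- function(rows) structure3d(rows)
  o <- sum(oracle_sasa(alone(a[a$chain == "A", ]), n_points = 960)) +
    sum(oracle_sasa(alone(a[a$chain == "B", ]), n_points = 960)) -
    sum(oracle_sasa(stack, n_points = 960))
  expect_equal(bur, o, tolerance = 0.02)  # quadrature frames differ
})

test_that("Kabsch superposition recovers rigid transforms", {
  set.seed(42)
  X <- matrix(rnorm(30), 10, 3)
  expect_lt(kabsch_superpose(X, X)$rmsd, 1e-12)

  th <- 1.1
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  Y <- X %*% R + matrix(rep(c(3, -1, 2), each = 10), 10, 3)
  k <- kabsch_superpose(X, Y)
  expect_lt(k$rmsd, 1e-10)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(X %*% k$rotation +
                      matrix(k$translation, 10, 3, byrow = TRUE) - Y)), 1e-9)
  expect_error(kabsch_superpose(X, X[1:5, ]), "matching")
})

test_that("Kabsch beats an exhaustive rotation-grid search", {
  # 4-point asymmetric set vs a noisy copy; SO(3) grid at 9 degrees
  X <- matrix(c(0, 0, 0, 1, 0, 0, 0, 2, 0, 0.3, 0.4, 1.5), 4, 3, byrow = TRUE)
  set.seed(7)
  Y <- X %*% diag(3) + matrix(rnorm(12, 0, 0.1), 4, 3)
  best <- Inf
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  for (a in seq(0, 350, 9) * pi / 180) for (b in seq(0, 170, 9) * pi / 180)
    for (c in seq(0, 350, 9) * pi / 180) {
      Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
      Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
      Rz2 <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
      r <- sqrt(mean(rowSums((Xc %*% (Rz %*% Ry %*% Rz2) - Yc)^2)))
      if (r < best) best <- r
    }
  k <- kabsch_superpose(X, Y)
  expect_lte(k$rmsd, best + 1e-12)        # optimal beats any grid point
  expect_lt(best - k$rmsd, 0.05)          # and the grid gets close
})

test_that("single-linkage clustering follows graph-component semantics", {
  tc <- generate_toy_complex(5, seed = 9)
  base <- tc$structure

  same <- rep(list(base), 4)
  cl <- cluster_frames_single_linkage(same, cutoff = 0.1)
  expect_length(cl$clusters, 1L)

  # two bundles separated by a large internal deformation
  frames <- deformed_frames(base, c(0, 0.01, 0.02, 2, 2.01))
  cl2 <- cluster_frames_single_linkage(frames, cutoff = 0.18)
  expect_length(cl2$clusters, 2L)
  expect_equal(sort(lengths(cl2$clusters)), c(2L, 3L))

  # chaining: A-B close, B-C close, A-C far => one cluster
  chain <- deformed_frames(base, c(0, 0.2, 0.4))
  m <- frame_rmsd_matrix(chain)
  cutoff <- m[1, 2] * 1.5  # between the step and the span
  expect_gt(m[1, 3], cutoff)
  cl3 <- cluster_frames_single_linkage(chain, cutoff = cutoff)
  expect_length(cl3$clusters, 1L)

  # frame-order invariance
  perm <- c(3, 1, 5, 2, 4)
  cl4 <- cluster_frames_single_linkage(frames[perm], cutoff = 0.18)
  relabel <- cl2$membership[perm]
  expect_equal(length(unique(relabel)), length(unique(cl4$membership)))
  expect_true(all(tapply(cl4$membership, relabel, function(z)
    length(unique(z))) == 1))

  # centroid minimizes summed within-cluster RMSD
  big <- which(lengths(cl2$clusters) == 3)
  members <- cl2$clusters[[big]]
  sums <- rowSums(cl2$rmsd[members, members, drop = FALSE])
  expect_equal(cl2$centroids[big], members[which.min(sums)])
})
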