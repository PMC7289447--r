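kT300 <- KB_KJ_MOL * 300

test_that("FES probabilities follow Boltzmann weights", {
  f <- free_energy_surface(list(c(0.1, 0.2, 0.3)), c(0, 0, 0), 300)
  p <- fes_to_probability(f)
  expect_equal(as.numeric(p), rep(1 / 3, 3))
  expect_equal(attr(p, "mean_coordinate"), 0.2)

  f2 <- free_energy_surface(list(c(0, 1)), c(0, kT300 * log(2)), 300)
  expect_equal(as.numeric(fes_to_probability(f2)), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  expect_equal(sum(fes_to_probability(f2)), 1, tolerance = 1e-12)
  expect_error(fes_to_probability(free_energy_surface(list(0:1), c(Inf, Inf), 300)),
               "finite")
})

test_that("four-state classification uses a strict bound threshold", {
  expect_equal(classify_state(0.40, 0.45), "both-bound")
  expect_equal(classify_state(0.60, 0.60), "both-unbound")
  expect_equal(classify_state(0.50, 0.40), "only-2")
  expect_equal(classify_state(0.40, 0.50), "only-1")
})

test_that("state populations integrate the Boltzmann weight per quadrant", {
  ax <- seq(0.305, 1.895, by = 0.01)
  flat <- free_energy_surface(list(ax, ax), matrix(0, 160, 160), 300)
  pops <- integrate_state_populations(flat, 0.5)
  expect_equal(unname(pops["both-bound"]), (0.2 / 1.6)^2, tolerance = 1e-12)
  expect_equal(sum(pops), 1)

  vals <- matrix(Inf, 160, 160)
  vals[ax < 0.5, ax >= 0.5] <- 0        # only-1 quadrant habitable
  f1 <- free_energy_surface(list(ax, ax), vals, 300)
  expect_equal(unname(integrate_state_populations(f1, 0.5)["only-1"]), 1)

  expect_error(integrate_state_populations(flat, 5), "outside the grid")
})

test_that("well-tempered bias converts to a free-energy surface", {
  gx <- seq(-1, 1, length.out = 81); gy <- seq(-1, 1, length.out = 81)
  zero <- bias_grid(gx, gy, matrix(0, 81, 81), 15, 300)
  expect_true(all(metad_bias_to_fes(zero)$values == 0))

  h <- 3
  g <- outer(gx, gy, function(x, y) h * exp(-(x^2 + y^2) / (2 * 0.04^2)))
  f <- metad_bias_to_fes(bias_grid(gx, gy, g, 15, 300))
  # well depth (gamma/(gamma-1)) h at the hill centre after re-zeroing
  expect_equal(max(f$values) - min(f$values), 15 / 14 * h, tolerance = 1e-6)
  expect_equal(which(f$values == min(f$values)), which(g == max(g)))

  # gauge: adding a constant to the bias leaves the FES unchanged
  f2 <- metad_bias_to_fes(bias_grid(gx, gy, g + 2, 15, 300))
  expect_equal(f2$values, f$values, tolerance = 1e-9)
  expect_error(bias_grid(gx, gy, g, 1, 300), "bias_factor")
})

test_that("block averaging aligns each map to its own minimum", {
  ax <- seq(0, 1, length.out = 11)
  base <- outer(ax, ax, function(x, y) 5 * (x - 0.5)^2 + 3 * y)
  f1 <- free_energy_surface(list(ax, ax), base, 300)
  same <- average_fes_blocks(list(f1, f1, f1))
  expect_equal(same$values, f1$values)
  expect_true(all(attr(same, "sd") == 0))

  # constant offsets are gauge and vanish after alignment
  f2 <- free_energy_surface(list(ax, ax), base + 7, 300)
  avg <- average_fes_blocks(list(f1, f2))
  expect_true(all(attr(avg, "sd") < 1e-12))
  # mean equals the brute-force mean of aligned maps
  noisy <- free_energy_surface(list(ax, ax), base + 0.3 * sin(10 * outer(ax, ax)), 300)
  avg2 <- average_fes_blocks(list(f1, noisy))
  manual <- (f1$values + noisy$values) / 2
  expect_equal(avg2$values, manual - min(manual), tolerance = 1e-12)

  bad <- free_energy_surface(list(ax[-1], ax[-1]), base[-1, -1], 300)
  expect_error(average_fes_blocks(list(f1, bad)), "same grid")
})

test_that("bias reweighting recovers unbiased observable profiles", {
  set.seed(4)
  coord <- runif(4000, 0, 1)
  obs <- 3 * coord + rnorm(4000, 0, 0.01)
  # unit weights: plain binned mean
  brk <- seq(0, 1, 0.1)
  rw0 <- reweight_observable(coord, obs, bias = rep(0, 4000),
                             offset = rep(0, 4000), 300, breaks = brk)
  manual <- tapply(obs, cut(coord, brk, include.lowest = TRUE), mean)
  expect_equal(rw0$mean, as.numeric(manual), tolerance = 1e-12)

  # weights enter only as ratios
  bias <- 0.5 * 30 * (coord - 0.5)^2
  rw1 <- reweight_observable(coord, obs, bias, 0, 300, breaks = brk)
  rw2 <- reweight_observable(coord, obs, bias + kT300 * log(2), 0, 300, breaks = brk)
  expect_equal(rw1$mean, rw2$mean, tolerance = 1e-9)

  # linear observable: recovered slope within 5%
  fitc <- coef(lm(mean ~ bin_center, data = rw1))[2]
  expect_lt(abs(fitc - 3) / 3, 0.05)

  # empty bins are NA, not zero
  rw3 <- reweight_observable(c(0.1, 0.9), c(1, 2), c(0, 0), 0, 300,
                             breaks = seq(0, 1, 0.25))
  expect_true(is.na(rw3$mean[2]))
  expect_equal(rw3$n[2], 0L)
})

test_that("umbrella samples have the analytic restraint statistics", {
  cfg <- simulation_config(seed = 11, n_steps = 200000L)
  uw <- sample_umbrella_windows(potential_flat(), centers = c(0.2, 0.4),
                                spring_k = 2500, config = cfg)
  for (w in uw$windows) {
    n_eff <- length(w$samples) / (2 * 1 / (2500 * cfg$langevin_dt))  # ~ n/2tau
    se_mean <- sqrt(kT300 / 2500 / n_eff)
    expect_lt(abs(mean(w$samples) - w$center), 3 * se_mean)
    expect_lt(abs(var(w$samples) - kT300 / 2500) / (kT300 / 2500), 0.1)
  }
  # determinism and error checking
  uw2 <- sample_umbrella_windows(potential_flat(), c(0.2, 0.4), 2500, cfg)
  expect_identical(uw$windows[[1]]$samples, uw2$windows[[1]]$samples)
  expect_error(sample_umbrella_windows(potential_flat(), 0.2, 2500,
                                       simulation_config(n_steps = 0)),
               "n_steps")
})

test_that("WHAM reproduces flat and harmonic reference profiles", {
  # unbiased uniform samples on a flat potential: flat FES
  set.seed(2)
  uw <- umbrella_window_set(0, 0, list(runif(1e5)), 300)
  res <- wham(uw, n_bins = 100)
  expect_true(res$converged)
  dev <- res$fes$values - mean(res$fes$values)
  expect_lt(max(abs(dev)), 0.2 * kT300)

  # windows with disconnected support are refused with the gap named
  uw_gap <- umbrella_window_set(c(0, 10), 2500,
                                list(rnorm(100, 0, 0.03), rnorm(100, 10, 0.03)),
                                300)
  expect_error(wham(uw_gap), "disconnected")
})

test_that("bootstrap errors scale like 1/sqrt(n) and are seed-stable", {
  kap <- 200
  mkwin <- function(n, seed) {
    set.seed(seed)
    centers <- seq(-0.1, 0.1, length.out = 3)
    umbrella_window_set(centers, 2500, lapply(centers, function(c0) {
      kw <- 2500 + kap
      rnorm(n, 2500 * c0 / kw, sqrt(kT300 / kw))
    }), 300)
  }
  se_small <- bootstrap_wham_errors(mkwin(1500, 1), n_boot = 60, seed = 3,
                                    n_bins = 30)
  se_big <- bootstrap_wham_errors(mkwin(6000, 1), n_boot = 60, seed = 3,
                                  n_bins = 30)
  ratio <- median(se_small / se_big, na.rm = TRUE)
  expect_gt(ratio, 1.4)   # ~2 expected for 4x the samples
  expect_lt(ratio, 2.9)

  se_a <- bootstrap_wham_errors(mkwin(1500, 1), n_boot = 150, seed = 7, n_bins = 30)
  se_b <- bootstrap_wham_errors(mkwin(1500, 1), n_boot = 150, seed = 8, n_bins = 30)
  expect_lt(abs(median(se_a, na.rm = TRUE) - median(se_b, na.rm = TRUE)) /
              median(se_a, na.rm = TRUE), 0.25)
  expect_error(bootstrap_wham_errors(mkwin(100, 1), n_boot = 1), "n_boot")
})

test_that("metadynamics bias accumulates monotonically and is deterministic", {
  pot <- potential2d_double_well(3, 0.5, 30)
  cfg_short <- simulation_config(seed = 9, n_steps = 20000L,
                                 deposition_stride = 100L)
  cfg_long <- simulation_config(seed = 9, n_steps = 60000L,
                                deposition_stride = 100L)
  r1 <- run_wt_metadynamics(pot, cfg_short, nx = 41, ny = 21, ylim = c(-0.5, 0.5))
  r1b <- run_wt_metadynamics(pot, cfg_short, nx = 41, ny = 21, ylim = c(-0.5, 0.5))
  expect_identical(r1$bias$values, r1b$bias$values)
  expect_identical(r1$traj, r1b$traj)

  # same seed, longer run: the shared prefix only adds bias
  r2 <- run_wt_metadynamics(pot, cfg_long, nx = 41, ny = 21, ylim = c(-0.5, 0.5))
  expect_true(all(r2$bias$values - r1$bias$values > -1e-9))
  expect_true(all(r1$bias$values >= 0))

  # no hills: plain Langevin, zero bias
  cfg0 <- simulation_config(seed = 9, n_steps = 5000L, hill_height = 0)
  r0 <- run_wt_metadynamics(pot, cfg0, nx = 41, ny = 21, ylim = c(-0.5, 0.5))
  expect_true(all(r0$bias$values == 0))
  expect_true(all(r0$traj$bias == 0))
})
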