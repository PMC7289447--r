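#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. Defaults follow
#' the conditions of the enhanced-sampling protocol the package emulates:
#' Gaussian hills of height 0.1 kJ/mol and width 0.04 nm deposited with a
#' well-tempered bias factor of 15, harmonic umbrella restraints of
#' 2500 kJ/mol/nm^2 (passed separately to [sample_umbrella_windows()]),
#' and a 300 K thermal energy. The evolutionary defaults describe a
#' 64-taxon ortholog family with conserved interface columns (rate 0.05
#' substitutions per unit branch length) and strongly coevolving pairs
#' (rate into the favoured profile s = 0.5, out d = 0.05).
#'
#' @param seed master seed (non-negative integer).
#' @param n_taxa number of leaves for tree simulation (>= 2).
#' @param birth_rate Yule birth rate (1/time, > 0).
#' @param n_sites number of alignment columns (>= 1).
#' @param coev_s,coev_d rate into / out of the coevolving profile (> 0).
#' @param langevin_dt integrator time step (> 0).
#' @param langevin_kT thermal energy in kJ/mol (> 0).
#' @param langevin_friction friction coefficient (> 0).
#' @param n_steps number of integrator steps (>= 0).
#' @param hill_height metadynamics hill height, kJ/mol (>= 0).
#' @param hill_width metadynamics hill width, nm (> 0).
#' @param deposition_stride steps between hill depositions (>= 1).
#' @param bias_factor well-tempered bias factor gamma (> 1).
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 0L,
                              n_taxa = 64L,
                              birth_rate = 1,
                              n_sites = 100L,
                              coev_s = 0.5,
                              coev_d = 0.05,
                              langevin_dt = 1e-5,
                              langevin_kT = KB_KJ_MOL * 300,
                              langevin_friction = 1,
                              n_steps = 100000L,
                              hill_height = 0.1,
                              hill_width = 0.04,
                              deposition_stride = 250L,
                              bias_factor = 15) {
  cfg <- list(seed = seed, n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
              n_sites = as.integer(n_sites), coev_s = coev_s, coev_d = coev_d,
              langevin_dt = langevin_dt, langevin_kT = langevin_kT,
              langevin_friction = langevin_friction, n_steps = as.integer(n_steps),
              hill_height = hill_height, hill_width = hill_width,
              deposition_stride = as.integer(deposition_stride),
              bias_factor = bias_factor)
  if (cfg$seed < 0) stop_invalid("seed must be non-negative")
  if (cfg$n_taxa < 2L) stop_invalid("n_taxa must be >= 2")
  if (cfg$n_sites < 1L) stop_invalid("n_sites must be >= 1")
  pos <- c("birth_rate", "coev_s", "coev_d", "langevin_dt", "langevin_kT",
           "langevin_friction", "hill_width")
  for (f in pos) if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
    stop_invalid(f, " must be strictly positive")
  if (cfg$n_steps < 0L) stop_invalid("n_steps must be >= 0")
  if (cfg$hill_height < 0) stop_invalid("hill_height must be >= 0")
  if (cfg$deposition_stride < 1L) stop_invalid("deposition_stride must be >= 1")
  if (cfg$bias_factor <= 1) stop_invalid("bias_factor must be > 1")
  structure(cfg, class = "sim_config")
}

#' Analytic test potentials
#'
#' Closed-form 1D and 2D potentials with known free energies, used as
#' ground truth by the biased-sampling generators and the free-energy
#' estimator tests. All energies in kJ/mol, coordinates in nm.
#'
#' * `potential_flat()`: U = 0.
#' * `potential_harmonic(kappa, x0)`: U = kappa/2 (x - x0)^2.
#' * `potential_double_well(height, a)`: U = height ((x/a)^2 - 1)^2 —
#'   minima at +/- a, barrier `height` at x = 0.
#' * `potential_linear(slope)`: U = slope * x.
#' * `potential2d_harmonic(kx, x0, ky, y0)`: separable harmonic.
#' * `potential2d_double_well(height, a, ky)`: double well along x plus a
#'   harmonic restraint along y.
#'
#' @param kappa,kx,ky harmonic force constants (kJ/mol/nm^2).
#' @param x0,y0 minima positions (nm).
#' @param height barrier height (kJ/mol).
#' @param a half-separation of the double-well minima (nm).
#' @param slope linear slope (kJ/mol/nm).
#' @return A `potential1d` / `potential2d` object: list with `type`,
#'   numeric `params`, and an energy function `U`.
#' @export
potential_flat <- function() {
  structure(list(type = 0L, params = 0, U = function(x) rep(0, length(x))),
            class = "potential1d")
}

#' @rdname potential_flat
#' @export
potential_harmonic <- function(kappa, x0 = 0) {
  structure(list(type = 1L, params = c(kappa, x0),
                 U = function(x) 0.5 * kappa * (x - x0)^2),
            class = "potential1d")
}

#' @rdname potential_flat
#' @export
potential_double_well <- function(height, a = 0.5) {
  structure(list(type = 2L, params = c(height, a),
                 U = function(x) height * ((x / a)^2 - 1)^2),
            class = "potential1d")
}

#' @rdname potential_flat
#' @export
potential_linear <- function(slope) {
  structure(list(type = 3L, params = slope, U = function(x) slope * x),
            class = "potential1d")
}

#' @rdname potential_flat
#' @export
potential2d_harmonic <- function(kx, x0 = 0, ky = kx, y0 = 0) {
  structure(list(type = 1L, params = c(kx, x0, ky, y0),
                 U = function(x, y) 0.5 * kx * (x - x0)^2 + 0.5 * ky * (y - y0)^2),
            class = "potential2d")
}

#' @rdname potential_flat
#' @export
potential2d_double_well <- function(height, a = 0.5, ky = 20) {
  structure(list(type = 2L, params = c(height, a, ky),
                 U = function(x, y) height * ((x / a)^2 - 1)^2 + 0.5 * ky * y^2),
            class = "potential2d")
}

#' @rdname potential_flat
#' @export
potential2d_flat <- function() {
  structure(list(type = 0L, params = 0, U = function(x, y) rep(0, length(x))),
            class = "potential2d")
}
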