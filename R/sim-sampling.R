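# Biased-sampling generators on analytic potentials: overdamped
# Euler-Maruyama Langevin dynamics (compiled core), with harmonic
# umbrella restraints or well-tempered metadynamics hill deposition.

#' Sample umbrella windows on an analytic 1D potential
#'
#' Per window, `config$n_steps` overdamped-Langevin samples of the
#' coordinate under `potential + k/2 (x - center)^2`. Each window has
#' its own deterministic RNG stream derived from `config$seed`.
#'
#' @param potential a 1D potential from [potential_harmonic()] etc.
#' @param centers restraint centres (nm).
#' @param spring_k restraint spring constant, kJ/mol/nm^2 (default 2500).
#' @param config a [simulation_config()].
#' @return An [umbrella_window_set()].
#' @export
sample_umbrella_windows <- function(potential, centers, spring_k = 2500,
                                    config = simulation_config()) {
  stopifnot(inherits(potential, "potential1d"), inherits(config, "sim_config"))
  if (!length(centers)) stop_invalid("need at least one window")
  if (config$n_steps < 1) stop_invalid("n_steps must be >= 1")
  samples <- lapply(seq_along(centers), function(i) {
    with_seed(split_seed(config$seed, paste0("umbrella", i)),
              c_langevin_umbrella(potential$type, as.numeric(potential$params),
                                  centers[i], spring_k, config$n_steps,
                                  config$langevin_dt, config$langevin_kT,
                                  config$langevin_friction, centers[i]))
  })
  umbrella_window_set(centers, spring_k, samples,
                      temperature = config$langevin_kT / KB_KJ_MOL)
}

#' Run well-tempered metadynamics on an analytic 2D potential
#'
#' Overdamped Langevin dynamics on two collective variables with
#' Gaussian hills of height `config$hill_height` and width
#' `config$hill_width` deposited every `config$deposition_stride`
#' steps, tempered by `exp(-V_bias/((gamma - 1) kT))`. The accumulated
#' bias is kept on a regular grid (bilinear interpolation for bias
#' forces); one-sided harmonic walls confine the walker to the grid.
#'
#' @param potential2d a 2D potential from [potential2d_double_well()]
#'   etc.
#' @param config a [simulation_config()].
#' @param xlim,ylim grid extent (nm).
#' @param nx,ny grid nodes per axis.
#' @param start c(x, y) initial position (default grid centre).
#' @param record_stride trajectory recording stride (steps).
#' @param wall_k wall force constant, kJ/mol/nm^2 (default 3000).
#' @return list with `traj` (data.frame `step,cv1,cv2,bias`) and `bias`
#'   (a [bias_grid()]).
#' @export
run_wt_metadynamics <- function(potential2d, config = simulation_config(),
                                xlim = c(-1, 1), ylim = c(-0.6, 0.6),
                                nx = 101L, ny = 61L, start = NULL,
                                record_stride = 100L, wall_k = 3000) {
  stopifnot(inherits(potential2d, "potential2d"), inherits(config, "sim_config"))
  if (config$hill_width <= 0) stop_invalid("hill_width must be > 0")
  if (config$bias_factor <= 1) stop_invalid("bias_factor must be > 1")
  if (is.null(start)) start <- c(mean(xlim), mean(ylim))
  res <- with_seed(split_seed(config$seed, "metad"),
    c_metadynamics(potential2d$type, as.numeric(potential2d$params),
                   config$n_steps, config$langevin_dt, config$langevin_kT,
                   config$langevin_friction, start[1], start[2],
                   config$hill_height, config$hill_width,
                   config$deposition_stride, config$bias_factor,
                   xlim[1], xlim[2], as.integer(nx),
                   ylim[1], ylim[2], as.integer(ny),
                   as.integer(record_stride), wall_k))
  traj <- as.data.frame(res$traj)
  names(traj) <- c("step", "cv1", "cv2", "bias")
  gx <- seq(xlim[1], xlim[2], length.out = nx)
  gy <- seq(ylim[1], ylim[2], length.out = ny)
  list(traj = traj,
       bias = bias_grid(gx, gy, res$bias, config$bias_factor,
                        config$langevin_kT / KB_KJ_MOL))
}
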