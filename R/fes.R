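# Free-energy surface containers and post-processing.

#' Free-energy surface
#'
#' A 1D or 2D grid of free energies (kJ/mol) on uniformly spaced bin
#' centres, with the minimum over finite bins set to zero. Unvisited
#' bins are `+Inf`.
#'
#' @param axes list of 1 or 2 numeric vectors of bin centres (nm,
#'   uniform spacing).
#' @param values numeric vector (1D) or matrix (2D, `length(axes[[1]])`
#'   rows) of free energies.
#' @param temperature temperature in K.
#' @return object of class `fes`.
#' @export
free_energy_surface <- function(axes, values, temperature) {
  if (!is.list(axes) || !length(axes) %in% 1:2) stop_invalid("axes must be 1 or 2 grids")
  for (ax in axes) {
    if (length(ax) > 1) {
      dsp <- diff(ax)
      if (max(abs(dsp - dsp[1])) > 1e-9 * max(abs(dsp)))
        stop_invalid("axis spacing must be uniform")
    }
  }
  if (length(axes) == 1) {
    values <- as.numeric(values)
    if (length(values) != length(axes[[1]])) stop_invalid("values/axis size mismatch")
  } else {
    values <- as.matrix(values)
    if (!all(dim(values) == c(length(axes[[1]]), length(axes[[2]]))))
      stop_invalid("values must be length(x) by length(y)")
  }
  fin <- is.finite(values)
  if (any(fin)) values <- values - min(values[fin])
  structure(list(axes = axes, values = values, temperature = temperature),
            class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  cat(sprintf("fes: %s grid, %d finite bins, max %.3f kJ/mol, T = %g K\n",
              paste(vapply(x$axes, length, integer(1)), collapse = " x "),
              sum(is.finite(x$values)),
              max(x$values[is.finite(x$values)]), x$temperature))
  invisible(x)
}

fes_kT <- function(fes) KB_KJ_MOL * fes$temperature

bin_width <- function(ax) if (length(ax) > 1) ax[2] - ax[1] else 1

#' Convert a free-energy surface to bin probabilities
#'
#' `p(bin)` proportional to `exp(-F/kT)` times the bin volume,
#' normalized to 1. The Boltzmann-weighted mean of each coordinate is
#' attached as attribute `mean_coordinate`.
#'
#' @param fes a [free_energy_surface()].
#' @return Probabilities with the shape of `fes$values`.
#' @export
fes_to_probability <- function(fes) {
  stopifnot(inherits(fes, "fes"))
  if (!any(is.finite(fes$values))) stop_invalid("no finite bins")
  w <- exp(-fes$values / fes_kT(fes))
  w[!is.finite(fes$values)] <- 0
  p <- w / sum(w)
  mc <- if (length(fes$axes) == 1) sum(p * fes$axes[[1]])
        else c(sum(rowSums(p) * fes$axes[[1]]), sum(colSums(p) * fes$axes[[2]]))
  attr(p, "mean_coordinate") <- mc
  p
}

#' Four-state classification of a double-distance coordinate
#'
#' A contact on coordinate `i` is formed iff `d_i < cutoff` (strict).
#'
#' @param d1,d2 distances in nm (vectorized).
#' @param cutoff contact threshold (default 0.5 nm).
#' @return Character vector in `{"both-bound", "only-1", "only-2",
#'   "both-unbound"}`.
#' @export
classify_state <- function(d1, d2, cutoff = 0.5) {
  b1 <- d1 < cutoff; b2 <- d2 < cutoff
  out <- character(length(b1))
  out[b1 & b2] <- "both-bound"
  out[b1 & !b2] <- "only-1"
  out[!b1 & b2] <- "only-2"
  out[!b1 & !b2] <- "both-unbound"
  out
}

#' Integrate four-state populations from a 2D free-energy surface
#'
#' Boltzmann weight `exp(-F/kT)` is integrated over the four quadrants
#' defined by [classify_state()] on the two axes (bins assigned by
#' centre) and normalized.
#'
#' @param fes2d a 2D [free_energy_surface()].
#' @param cutoff contact threshold in nm (must lie inside both axes).
#' @return Named numeric vector of the four populations, summing to 1.
#' @export
integrate_state_populations <- function(fes2d, cutoff = 0.5) {
  stopifnot(inherits(fes2d, "fes"))
  if (length(fes2d$axes) != 2) stop_invalid("need a 2D surface")
  for (ax in fes2d$axes)
    if (cutoff <= min(ax) - bin_width(ax) / 2 || cutoff >= max(ax) + bin_width(ax) / 2)
      stop_invalid("cutoff lies outside the grid")
  p <- fes_to_probability(fes2d)
  lab <- outer(fes2d$axes[[1]], fes2d$axes[[2]],
               function(a, b) classify_state(a, b, cutoff))
  states <- c("both-bound", "only-1", "only-2", "both-unbound")
  pops <- vapply(states, function(s) sum(p[lab == s]), numeric(1))
  pops / sum(pops)
}

#' Bias grid accumulated by well-tempered metadynamics
#'
#' @param x,y grid node coordinates (nm).
#' @param values accumulated bias (kJ/mol), `length(x)` by `length(y)`,
#'   all non-negative.
#' @param bias_factor well-tempered factor gamma (> 1).
#' @param temperature temperature in K.
#' @return object of class `bias_grid`.
#' @export
bias_grid <- function(x, y, values, bias_factor, temperature) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(x), ncol(values) == length(y))
  if (any(values < -1e-9)) stop_invalid("bias values must be >= 0")
  if (bias_factor <= 1) stop_invalid("bias_factor must be > 1")
  structure(list(x = x, y = y, values = values, bias_factor = bias_factor,
                 temperature = temperature), class = "bias_grid")
}

#' Free-energy surface from a well-tempered bias
#'
#' The well-tempered estimator `F(s) = -gamma/(gamma-1) V_bias(s)`,
#' re-zeroed at its minimum.
#'
#' @param bias a [bias_grid()].
#' @return A 2D [free_energy_surface()].
#' @export
metad_bias_to_fes <- function(bias) {
  stopifnot(inherits(bias, "bias_grid"))
  g <- bias$bias_factor
  if (g <= 1) stop_invalid("bias_factor must be > 1")
  free_energy_surface(list(bias$x, bias$y), -g / (g - 1) * bias$values,
                      bias$temperature)
}

#' Average free-energy maps over blocks
#'
#' Each map is re-zeroed at its own finite minimum (the free-energy
#' gauge is arbitrary), then averaged per bin; the per-bin standard
#' deviation is attached as attribute `sd`.
#'
#' @param fes_list list of [free_energy_surface()] on identical grids.
#' @return The mean `fes` with attribute `sd`.
#' @export
average_fes_blocks <- function(fes_list) {
  stopifnot(length(fes_list) >= 1, all(vapply(fes_list, inherits, logical(1), "fes")))
  ref <- fes_list[[1]]
  for (f in fes_list)
    if (!identical(lapply(f$axes, length), lapply(ref$axes, length)) ||
        max(abs(unlist(f$axes) - unlist(ref$axes))) > 1e-9)
      stop_invalid("all maps must share the same grid")
  arr <- vapply(fes_list, function(f) {
    v <- f$values
    fin <- is.finite(v)
    v[fin] <- v[fin] - min(v[fin])  # re-zero (already zeroed on construction)
    as.vector(v)
  }, numeric(length(ref$values)))
  mn <- rowMeans(arr)
  sdv <- apply(arr, 1, function(z) if (all(is.finite(z))) sd(z) else NA_real_)
  if (length(fes_list) == 1) sdv[] <- 0
  out <- free_energy_surface(ref$axes,
                             if (is.matrix(ref$values)) matrix(mn, nrow(ref$values))
                             else mn,
                             ref$temperature)
  attr(out, "sd") <- if (is.matrix(ref$values)) matrix(sdv, nrow(ref$values)) else sdv
  out
}

#' Reweight an observable measured under umbrella biases
#'
#' Frames sampled in biased windows are reweighted with
#' `exp((U_i(r) - F_i)/kT)`, where `U_i(r)` is the bias energy of the
#' frame and `F_i` the free-energy offset of its window (from
#' [wham()]); the observable's weighted mean is reported per coordinate
#' bin. Empty bins are reported as `NA`, not zero.
#'
#' @param coord coordinate value per frame (nm).
#' @param obs observable value per frame.
#' @param bias bias energy `U_i(r)` per frame (kJ/mol).
#' @param offset window offset `F_i` per frame (kJ/mol).
#' @param temperature temperature in K.
#' @param breaks bin breaks, or a single bin count over the coordinate
#'   range.
#' @return data.frame with `bin_center`, weighted `mean`, and frame
#'   count `n` per bin.
#' @export
reweight_observable <- function(coord, obs, bias, offset, temperature,
                                breaks = 25) {
  stopifnot(length(coord) == length(obs), length(bias) == length(coord),
            length(offset) %in% c(1, length(coord)))
  if (length(breaks) == 1) breaks <- seq(min(coord), max(coord), length.out = breaks + 1)
  kT <- KB_KJ_MOL * temperature
  logw <- (bias - offset) / kT
  logw <- logw - max(logw)  # weights enter only as ratios
  w <- exp(logw)
  idx <- cut(coord, breaks, include.lowest = TRUE, labels = FALSE)
  centers <- (head(breaks, -1) + breaks[-1]) / 2
  out <- data.frame(bin_center = centers, mean = NA_real_,
                    n = tabulate(idx, nbins = length(centers)))
  for (b in which(out$n > 0)) {
    sel <- which(idx == b)
    out$mean[b] <- sum(w[sel] * obs[sel]) / sum(w[sel])
  }
  out
}
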