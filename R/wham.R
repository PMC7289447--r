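#' Umbrella window set
#'
#' Harmonically restrained samples of a scalar collective variable.
#'
#' @param centers restraint centres (nm), one per window.
#' @param spring_k spring constant(s), kJ/mol/nm^2 (recycled).
#' @param samples list of numeric sample vectors, one per window.
#' @param temperature temperature in K.
#' @return object of class `umbrella_windows`.
#' @export
umbrella_window_set <- function(centers, spring_k, samples, temperature = 300) {
  if (length(samples) != length(centers)) stop_invalid("one sample vector per window")
  spring_k <- rep_len(spring_k, length(centers))
  if (any(spring_k < 0)) stop_invalid("spring_k must be >= 0")
  if (any(vapply(samples, length, integer(1)) < 1))
    stop_invalid("every window needs at least one sample")
  structure(list(windows = lapply(seq_along(centers), function(i)
    list(center = centers[i], spring_k = spring_k[i],
         samples = as.numeric(samples[[i]]))),
    temperature = temperature), class = "umbrella_windows")
}

#' @export
print.umbrella_windows <- function(x, ...) {
  cat(sprintf("umbrella_windows: %d windows, %s samples each, T = %g K\n",
              length(x$windows),
              paste(range(vapply(x$windows, function(w) length(w$samples), integer(1))),
                    collapse = "-"), x$temperature))
  invisible(x)
}

# connected support check on per-window sample intervals
check_window_overlap <- function(windows) {
  iv <- t(vapply(windows$windows, function(w) range(w$samples), numeric(2)))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  hi <- iv[1, 2]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] > hi)
      stop_invalid(sprintf(
        "histogram support is disconnected: no samples in (%.4f, %.4f) nm",
        hi, iv[i, 1]))
    hi <- max(hi, iv[i, 2])
  }
  invisible(TRUE)
}

#' Weighted histogram analysis (WHAM)
#'
#' Self-consistent combination of biased window histograms into one
#' unbiased free-energy profile. Bins default to 100 spanning the
#' pooled sample range; unvisited bins are `+Inf` and never
#' extrapolated.
#'
#' @param windows an [umbrella_window_set()].
#' @param n_bins number of histogram bins (default 100).
#' @param tol convergence tolerance on the window offsets F_i (kJ/mol).
#' @param max_iter maximum self-consistency iterations.
#' @param breaks optional explicit bin breaks (overrides `n_bins`).
#' @return list with `fes` (1D [free_energy_surface()]), `offsets`
#'   (per-window free energies F_i, kJ/mol, first window = 0),
#'   `converged`, and `n_iter`.
#' @export
wham <- function(windows, n_bins = 100, tol = 1e-8, max_iter = 10000,
                 breaks = NULL) {
  stopifnot(inherits(windows, "umbrella_windows"))
  check_window_overlap(windows)
  kT <- KB_KJ_MOL * windows$temperature
  all_x <- unlist(lapply(windows$windows, `[[`, "samples"))
  if (is.null(breaks)) breaks <- seq(min(all_x), max(all_x), length.out = n_bins + 1)
  centers <- (head(breaks, -1) + breaks[-1]) / 2
  nb <- length(centers); nw <- length(windows$windows)

  counts <- vapply(windows$windows, function(w) {
    idx <- cut(w$samples, breaks, include.lowest = TRUE, labels = FALSE)
    tabulate(idx[!is.na(idx)], nbins = nb)
  }, numeric(nb))                       # nb x nw
  Ni <- colSums(counts)
  numer <- rowSums(counts)
  # bias energies of each window at each bin centre
  U <- vapply(windows$windows, function(w)
    0.5 * w$spring_k * (centers - w$center)^2, numeric(nb))
  C <- exp(-U / kT)                     # nb x nw

  Fi <- numeric(nw)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    denom <- as.vector(C %*% (Ni * exp(Fi / kT)))
    p <- ifelse(denom > 0, numer / denom, 0)
    if (sum(p) == 0) stop("WHAM failed: empty histograms")
    p <- p / sum(p)
    Fi_new <- -kT * log(as.vector(crossprod(C, p)))
    Fi_new <- Fi_new - Fi_new[1]
    delta <- max(abs(Fi_new - Fi))
    Fi <- Fi_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("WHAM did not converge to ", tol, " in ", max_iter,
                          " iterations (last change ", signif(delta, 3), ")")
  Fv <- ifelse(p > 0, -kT * log(p), Inf)
  list(fes = free_energy_surface(list(centers), Fv, windows$temperature),
       offsets = Fi, converged = converged, n_iter = it)
}

#' Bootstrap standard errors for a WHAM profile
#'
#' Monte Carlo bootstrap: each window's samples are resampled with
#' replacement and WHAM is re-solved on the same bin grid; the per-bin
#' standard deviation over replicates is the error estimate.
#'
#' @param windows an [umbrella_window_set()].
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed RNG seed.
#' @param ... passed to [wham()].
#' @return Numeric vector of per-bin standard errors (`NA` where any
#'   replicate left the bin empty), with bin centres in attribute
#'   `centers`.
#' @export
bootstrap_wham_errors <- function(windows, n_boot = 50, seed = 0L, ...) {
  if (n_boot < 2) stop_invalid("n_boot must be >= 2")
  full <- wham(windows, ...)
  breaks0 <- {
    ax <- full$fes$axes[[1]]
    h <- bin_width(ax) / 2
    c(ax - h, ax[length(ax)] + h)
  }
  profiles <- with_seed(split_seed(seed, "wham_boot"), {
    vapply(seq_len(n_boot), function(b) {
      ws <- windows
      ws$windows <- lapply(ws$windows, function(w) {
        w$samples <- sample(w$samples, length(w$samples), replace = TRUE)
        w
      })
      res <- suppressWarnings(wham(ws, breaks = breaks0, ...))
      res$fes$values
    }, numeric(length(full$fes$values)))
  })
  se <- apply(profiles, 1, function(z)
    if (all(is.finite(z))) sd(z) else NA_real_)
  attr(se, "centers") <- full$fes$axes[[1]]
  se
}
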