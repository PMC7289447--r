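# Shrake-Rupley solvent-accessible surface area on a deterministic
# golden-spiral quadrature. Radii are element-based (Bondi set), in nm.

#' @export
VDW_RADII_NM <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152,
                  S = 0.180, P = 0.180)

# express coordinates in a deterministic molecule-fixed frame: centroid at
# the origin, axes along the covariance eigenvectors with fixed signs
canonical_frame <- function(xyz) {
  if (nrow(xyz) < 3) return(sweep(xyz, 2, colMeans(xyz)))
  xc <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(xc), symmetric = TRUE)$vectors
  for (j in 1:3) {
    k <- which.max(abs(ev[, j]))
    if (ev[k, j] < 0) ev[, j] <- -ev[, j]
  }
  if (det(ev) < 0) ev[, 3] <- -ev[, 3]
  xc %*% ev
}

# n roughly evenly distributed unit vectors (golden-section spiral)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by test-point quadrature: `n_points` points are placed
#' on each atom's solvent-expanded sphere (radius + probe) and counted
#' as accessible when outside every neighbouring expanded sphere.
#'
#' @param s a [structure3d()].
#' @param probe probe radius in nm (default 0.14, a water molecule).
#' @param n_points quadrature points per atom (default 960).
#' @param radii named element-radius vector in nm (default Bondi set).
#' @param default_radius radius assigned (with a warning) to elements
#'   missing from `radii`.
#' @return Numeric vector of per-atom areas in nm^2; `sum()` gives the
#'   total surface.
#' @export
shrake_rupley_sasa <- function(s, probe = 0.14, n_points = 960L,
                               radii = VDW_RADII_NM, default_radius = 0.17,
                               orient = TRUE) {
  a <- s$atoms
  n <- nrow(a)
  if (n == 0) return(numeric(0))
  r <- radii[a$element]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(a$element[is.na(r)]), collapse = " "),
            "; using default radius ", default_radius, " nm")
    r[is.na(r)] <- default_radius
  }
  r <- unname(r) + probe
  # quadrature points are oriented in a molecule-fixed (principal-axes)
  # frame so the areas are invariant under rigid-body motion; `orient =
  # FALSE` keeps the caller's frame (used when comparing sub-structures)
  xyz <- if (orient) canonical_frame(coords(s)) else coords(s)
  pts <- sphere_points(n_points)
  d <- cross_dist(xyz, xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(seq_len(n) != i & d[i, ] < r[i] + r)
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      pd <- cross_dist(p, xyz[nb, , drop = FALSE])
      free <- rowSums(pd < rep(r[nb], each = n_points)) == 0
    } else {
      free <- rep(TRUE, n_points)
    }
    area[i] <- 4 * pi * r[i]^2 * mean(free)
  }
  area
}

#' @export
HYDROPHOBIC_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")

#' Buried hydrophobic surface of a two-chain interface
#'
#' Difference between the solvent-exposed surface of hydrophobic
#' residues in the dissociated chains and in the bound complex.
#'
#' @param bound a [structure3d()] containing both chains.
#' @param chainA,chainB chain identifiers.
#' @param hydrophobic residue names counted as hydrophobic (glycine is
#'   excluded by default).
#' @param ... passed to [shrake_rupley_sasa()].
#' @return Buried hydrophobic area in nm^2.
#' @export
buried_hydrophobic_area <- function(bound, chainA, chainB,
                                    hydrophobic = HYDROPHOBIC_RESIDUES, ...) {
  a <- bound$atoms
  if (!all(c(chainA, chainB) %in% a$chain)) stop_invalid("both chains must be present")
  # one shared quadrature frame (that of the complex) so the bound and
  # dissociated terms cancel exactly where there is no occlusion
  both <- a[a$chain %in% c(chainA, chainB), , drop = FALSE]
  xyz <- canonical_frame(as.matrix(both[c("x", "y", "z")]))
  both$x <- xyz[, 1]; both$y <- xyz[, 2]; both$z <- xyz[, 3]
  hyd_sum <- function(rows) {
    s <- structure3d(rows)
    area <- shrake_rupley_sasa(s, orient = FALSE, ...)
    sum(area[rows$resname %in% hydrophobic])
  }
  hyd_sum(both[both$chain %in% chainA, , drop = FALSE]) +
    hyd_sum(both[both$chain %in% chainB, , drop = FALSE]) -
    hyd_sum(both)
}
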