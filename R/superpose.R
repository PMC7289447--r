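#' Kabsch superposition
#'
#' Optimal rigid-body superposition of two matched coordinate sets by
#' singular value decomposition, constrained to a proper rotation
#' (determinant +1).
#'
#' @param X,Y n x 3 coordinate matrices (nm), matched row by row; n >= 3.
#' @return list with `rotation` (3 x 3), `translation` (length 3) such
#'   that `X %*% rotation + translation` best fits `Y`, and `rmsd` (nm).
#' @export
kabsch_superpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop_invalid("X and Y must have matching dimensions")
  if (nrow(X) < 3) stop_invalid("need at least 3 points")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  dsign <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, dsign)) %*% t(sv$v)
  t_vec <- cy - as.vector(cx %*% R)
  fit <- Xc %*% R
  rmsd <- sqrt(mean(rowSums((fit - Yc)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

# atom indices used for fitting/measuring: chain/residue selection plus an
# optional atom-name filter (e.g. CA-only for backbone clustering)
frame_sel_idx <- function(s, sel = NULL, atom_names = NULL) {
  idx <- if (is.null(sel)) seq_len(nrow(s$atoms)) else sel_atom_idx(s, sel)
  if (!is.null(atom_names)) idx <- idx[s$atoms$atom[idx] %in% atom_names]
  idx
}

#' Pairwise RMSD matrix of a frame list
#'
#' Each pair of frames is superposed with [kabsch_superpose()] on the
#' fit selection, then RMSD is measured on the measurement selection.
#'
#' @param frames list of [structure3d()] with identical atom ordering.
#' @param sel measurement selection (`NULL` = all atoms).
#' @param atom_names optional atom-name filter (e.g. `"CA"`).
#' @param fit_sel,fit_atom_names selection used for superposition
#'   (defaults to the measurement selection).
#' @return Symmetric matrix of RMSD values in nm.
#' @export
frame_rmsd_matrix <- function(frames, sel = NULL, atom_names = NULL,
                              fit_sel = sel, fit_atom_names = atom_names) {
  n <- length(frames)
  meas <- frame_sel_idx(frames[[1]], sel, atom_names)
  fit <- frame_sel_idx(frames[[1]], fit_sel, fit_atom_names)
  if (length(fit) < 3) stop_invalid("fit selection must contain >= 3 atoms")
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    k <- kabsch_superpose(coords(frames[[i]], fit), coords(frames[[j]], fit))
    xi <- sweep(coords(frames[[i]], meas), 2, colMeans(coords(frames[[i]], fit))) %*%
      k$rotation
    xj <- sweep(coords(frames[[j]], meas), 2, colMeans(coords(frames[[j]], fit)))
    m[i, j] <- m[j, i] <- sqrt(mean(rowSums((xi - xj)^2)))
  }
  m
}

#' Single-linkage RMSD clustering of frames
#'
#' Clusters are the connected components of the graph whose edges join
#' frames with pairwise RMSD strictly below `cutoff` (single-linkage
#' semantics). Each cluster's centroid is the frame minimizing the
#' summed RMSD to the other members.
#'
#' @inheritParams frame_rmsd_matrix
#' @param cutoff RMSD cutoff in nm (strict `<`).
#' @return list with `membership` (integer vector, cluster id per frame,
#'   ordered by decreasing cluster size), `clusters` (list of member
#'   indices), `centroids` (centroid frame index per cluster), and the
#'   RMSD matrix.
#' @export
cluster_frames_single_linkage <- function(frames, cutoff, sel = NULL,
                                          atom_names = NULL, fit_sel = sel,
                                          fit_atom_names = atom_names) {
  if (!length(frames)) stop_invalid("need at least one frame")
  m <- frame_rmsd_matrix(frames, sel, atom_names, fit_sel, fit_atom_names)
  n <- length(frames)
  # union-find over edges m < cutoff (strict), invariant to frame order
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    if (m[i, j] < cutoff) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- unique(roots)
  sizes <- vapply(ids, function(r) sum(roots == r), integer(1))
  ids <- ids[order(-sizes, ids)]
  membership <- match(roots, ids)
  clusters <- lapply(seq_along(ids), function(k) which(membership == k))
  centroids <- vapply(clusters, function(cl) {
    if (length(cl) == 1) return(cl)
    cl[which.min(rowSums(m[cl, cl, drop = FALSE]))]
  }, integer(1))
  list(membership = membership, clusters = clusters,
       centroids = centroids, rmsd = m)
}
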