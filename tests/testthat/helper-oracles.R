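# Independent brute-force oracles and small fixture builders.
# These deliberately use naive double loops and their own geometry code so
# they stay independent of the package implementation they check.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

atoms_of <- function(s) s$atoms

# naive all-pairs cross-chain heavy-atom contact count
oracle_contacts <- function(s, chainA, chainB, cutoff = 0.5) {
  a <- s$atoms
  ia <- which(a$chain == chainA & a$element != "H")
  ib <- which(a$chain == chainB & a$element != "H")
  n <- 0L
  pairs <- list()
  for (i in ia) for (j in ib) {
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
    if (d < cutoff) {
      n <- n + 1L
      pairs[[n]] <- c(a$resno[i], a$resno[j])
    }
  }
  list(count = n, res_pairs = unique(do.call(rbind, pairs)))
}

ORACLE_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
ORACLE_GROUPS <- list(ARG = c("NE", "CZ", "NH1", "NH2"), LYS = "NZ",
                      ASP = c("CG", "OD1", "OD2"), GLU = c("CD", "OE1", "OE2"))
ORACLE_SIGN <- c(ARG = 1, LYS = 1, ASP = -1, GLU = -1)

oracle_ion_pairs <- function(s, cutoff = 0.5) {
  a <- s$atoms
  groups <- list()
  for (key in unique(paste(a$chain, a$resno))) {
    rr <- a[paste(a$chain, a$resno) == key, ]
    rn <- rr$resname[1]
    if (!rn %in% names(ORACLE_GROUPS)) next
    sel <- rr[rr$atom %in% ORACLE_GROUPS[[rn]], ]
    if (nrow(sel) < length(ORACLE_GROUPS[[rn]])) next
    m <- ORACLE_MASS[sel$element]
    groups[[length(groups) + 1L]] <- list(
      chain = rr$chain[1], resno = rr$resno[1], sign = ORACLE_SIGN[rn],
      com = c(sum(sel$x * m), sum(sel$y * m), sum(sel$z * m)) / sum(m))
  }
  out <- 0L
  ids <- list()
  if (length(groups) >= 2)
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      gi <- groups[[i]]; gj <- groups[[j]]
      if (gi$sign <= 0 || gj$sign >= 0) next
      if (sqrt(sum((gi$com - gj$com)^2)) < cutoff) {
        out <- out + 1L
        ids[[out]] <- c(gi$chain, gi$resno, gj$chain, gj$resno)
      }
    }
  list(count = out, ids = ids)
}

oracle_hbonds <- function(s, d_cut = 0.35, angle_cut = 30) {
  a <- s$atoms
  xyz <- as.matrix(a[c("x", "y", "z")])
  polar <- which(a$element %in% c("N", "O"))
  hyd <- which(a$element == "H")
  found <- 0L
  for (di in polar) {
    hs <- c()
    for (h in hyd)
      if (sqrt(sum((xyz[h, ] - xyz[di, ])^2)) < 0.125) hs <- c(hs, h)
    if (!length(hs)) next
    for (ai in polar) {
      if (ai == di) next
      if (a$chain[ai] == a$chain[di] && a$resno[ai] == a$resno[di]) next
      dda <- sqrt(sum((xyz[ai, ] - xyz[di, ])^2))
      if (dda >= d_cut) next
      best <- Inf
      for (h in hs) {
        vh <- xyz[h, ] - xyz[di, ]; va <- xyz[ai, ] - xyz[di, ]
        ang <- acos(max(-1, min(1, sum(vh * va) /
                                  sqrt(sum(vh^2) * sum(va^2))))) * 180 / pi
        best <- min(best, ang)
      }
      if (best < angle_cut) found <- found + 1L
    }
  }
  found
}

# naive Shrake-Rupley with the same deterministic point set and the same
# molecule-fixed quadrature frame convention
oracle_frame <- function(xyz) {
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

oracle_sasa <- function(s, probe = 0.14, n_points = 120) {
  a <- s$atoms
  radii <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180, P = 0.180)
  r <- unname(radii[a$element]) + probe
  k <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * k / n_points)
  theta <- pi * (1 + sqrt(5)) * k
  pts <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  xyz <- oracle_frame(as.matrix(a[c("x", "y", "z")]))
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in seq_len(nrow(a))) {
      if (j == i) next
      dj <- sqrt(rowSums(sweep(p, 2, xyz[j, ])^2))
      acc <- acc & dj >= r[j]
    }
    out[i] <- 4 * pi * r[i]^2 * mean(acc)
  }
  out
}

# tiny deterministic structure builders
atom_row <- function(chain, resno, resname, atom, element, x, y, z) {
  data.frame(chain = chain, resno = resno, resname = resname, atom = atom,
             element = element, x = x, y = y, z = z, stringsAsFactors = FALSE)
}

two_carbons <- function(d) {
  structure3d(rbind(
    atom_row("A", 1, "ALA", "CA", "C", 0, 0, 0),
    atom_row("B", 1, "ALA", "CA", "C", d, 0, 0)))
}

# a frame list with controlled internal deformation (non-rigid)
deformed_frames <- function(base, shifts) {
  lapply(shifts, function(dz) {
    s <- base
    n <- nrow(s$atoms)
    s$atoms$z <- s$atoms$z + dz * (seq_len(n) %% 2)  # alternate atoms move
    s
  })
}
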