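# Geometric interface detectors. All cutoffs are strict (<) and all
# distances are in nm. Selections are either chain ids or data.frames
# with columns `chain` and `resno`.

sel_atom_idx <- function(s, sel) {
  a <- s$atoms
  if (is.character(sel)) return(which(a$chain %in% sel))
  if (is.data.frame(sel) && all(c("chain", "resno") %in% names(sel)))
    return(which(paste(a$chain, a$resno) %in% paste(sel$chain, sel$resno)))
  stop_invalid("selection must be chain id(s) or a data.frame(chain, resno)")
}

#' Count cross-interface atom contacts
#'
#' Contacts are pairs of non-hydrogen atoms, one from each selection,
#' closer than `cutoff` (strictly). Results are aggregated per residue
#' pair and per interface side.
#'
#' @param s a [structure3d()].
#' @param selA,selB disjoint residue selections (chain ids or
#'   `data.frame(chain, resno)`).
#' @param cutoff contact distance cutoff in nm (default 0.5).
#' @return A `contact_report`: list with `atom_contact_count`,
#'   `residue_pairs` (data.frame `chainA,resA,chainB,resB,n_contacts`),
#'   and the interface residue sets of both sides.
#' @export
interface_contacts <- function(s, selA, selB, cutoff = 0.5) {
  ia <- sel_atom_idx(s, selA)
  ib <- sel_atom_idx(s, selB)
  if (length(intersect(ia, ib)))
    stop_invalid("selections overlap: interface selections must be disjoint")
  a <- s$atoms
  ia <- ia[a$element[ia] != "H"]
  ib <- ib[a$element[ib] != "H"]
  d <- cross_dist(coords(s, ia), coords(s, ib))
  hit <- which(d < cutoff, arr.ind = TRUE)
  if (nrow(hit)) {
    key <- data.frame(chainA = a$chain[ia[hit[, 1]]], resA = a$resno[ia[hit[, 1]]],
                      chainB = a$chain[ib[hit[, 2]]], resB = a$resno[ib[hit[, 2]]],
                      stringsAsFactors = FALSE)
    agg <- stats::aggregate(list(n_contacts = rep(1L, nrow(key))),
                            key, FUN = sum)
    agg <- agg[order(agg$chainA, agg$resA, agg$chainB, agg$resB), ]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(chainA = character(), resA = integer(),
                      chainB = character(), resB = integer(),
                      n_contacts = integer())
  }
  structure(list(
    atom_contact_count = nrow(hit),
    residue_pairs = agg,
    interface_residues_A = unique(agg[c("chainA", "resA")]),
    interface_residues_B = unique(agg[c("chainB", "resB")])
  ), class = "contact_report")
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf("contact_report: %d atom contacts over %d residue pairs (%d vs %d interface residues)\n",
              x$atom_contact_count, nrow(x$residue_pairs),
              nrow(x$interface_residues_A), nrow(x$interface_residues_B)))
  invisible(x)
}

# side-chain charged groups: residue name -> member atoms and sign
CHARGED_GROUPS <- list(
  ARG = list(atoms = c("NE", "CZ", "NH1", "NH2"), sign = +1L),
  LYS = list(atoms = "NZ", sign = +1L),
  ASP = list(atoms = c("CG", "OD1", "OD2"), sign = -1L),
  GLU = list(atoms = c("CD", "OE1", "OE2"), sign = -1L)
)

# mass-weighted centres of all complete charged groups in a structure
charged_group_coms <- function(s) {
  a <- s$atoms
  out <- list()
  for (rn in names(CHARGED_GROUPS)) {
    g <- CHARGED_GROUPS[[rn]]
    rows <- a[a$resname == rn, , drop = FALSE]
    if (!nrow(rows)) next
    for (key in unique(paste(rows$chain, rows$resno))) {
      rr <- rows[paste(rows$chain, rows$resno) == key, , drop = FALSE]
      gr <- rr[rr$atom %in% g$atoms, , drop = FALSE]
      if (nrow(gr) < length(g$atoms)) {
        warning("charged group of ", rn, " ", key,
                " is missing atoms; group skipped")
        next
      }
      m <- ATOM_MASSES[gr$element]
      m[is.na(m)] <- 12
      com <- colSums(as.matrix(gr[c("x", "y", "z")]) * m) / sum(m)
      out[[length(out) + 1L]] <- data.frame(
        chain = gr$chain[1], resno = gr$resno[1], resname = rn, sign = g$sign,
        x = com[1], y = com[2], z = com[3], stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(chain = character(), resno = integer(), resname = character(),
                  sign = integer(), x = numeric(), y = numeric(), z = numeric())
}

#' Detect ion pairs
#'
#' Ion pairs are pairs of oppositely charged side-chain groups (Arg
#' guanidine, Lys amine, Asp/Glu carboxylate) whose mass-weighted group
#' centres of mass are closer than `cutoff` (strictly). Terminal
#' amine/carboxylate groups are not considered.
#'
#' @param s a [structure3d()].
#' @param cutoff COM distance cutoff in nm (default 0.5).
#' @return data.frame with the positive-group residue, negative-group
#'   residue and COM distance of every ion pair.
#' @export
detect_ion_pairs <- function(s, cutoff = 0.5) {
  g <- charged_group_coms(s)
  pos <- g[g$sign > 0, , drop = FALSE]
  neg <- g[g$sign < 0, , drop = FALSE]
  empty <- data.frame(chainP = character(), resP = integer(), resnameP = character(),
                      chainN = character(), resN = integer(), resnameN = character(),
                      dist = numeric())
  if (!nrow(pos) || !nrow(neg)) return(empty)
  d <- cross_dist(as.matrix(pos[c("x", "y", "z")]), as.matrix(neg[c("x", "y", "z")]))
  hit <- which(d < cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  out <- data.frame(chainP = pos$chain[hit[, 1]], resP = pos$resno[hit[, 1]],
                    resnameP = pos$resname[hit[, 1]],
                    chainN = neg$chain[hit[, 2]], resN = neg$resno[hit[, 2]],
                    resnameN = neg$resname[hit[, 2]],
                    dist = d[hit], stringsAsFactors = FALSE)
  out[order(out$chainP, out$resP, out$chainN, out$resN), , drop = FALSE]
}

#' Detect hydrogen bonds
#'
#' Standard geometric criterion: donor-acceptor distance below `d_cut`
#' and hydrogen-donor-acceptor angle below `angle_cut`. Donors are N/O
#' atoms carrying at least one hydrogen (an H atom within 0.125 nm);
#' acceptors are N/O atoms. If the structure contains no hydrogens at
#' all, the angle test is skipped and the distance criterion alone is
#' applied, with a message.
#'
#' @param s a [structure3d()].
#' @param d_cut donor-acceptor cutoff, nm (default 0.35).
#' @param angle_cut H-donor-acceptor cutoff, degrees (default 30).
#' @return data.frame of donor, acceptor, distance (nm) and angle
#'   (degrees; `NA` in distance-only mode).
#' @export
detect_hbonds <- function(s, d_cut = 0.35, angle_cut = 30) {
  a <- s$atoms
  xyz <- coords(s)
  is_h <- a$element == "H"
  polar <- which(a$element %in% c("N", "O"))
  have_h <- any(is_h)

  # attach hydrogens to their nearest polar atom within the covalent range
  donor_h <- vector("list", nrow(a))
  if (have_h) {
    hidx <- which(is_h)
    if (length(polar) && length(hidx)) {
      dh <- cross_dist(xyz[polar, , drop = FALSE], xyz[hidx, , drop = FALSE])
      for (k in seq_along(hidx)) {
        j <- which.min(dh[, k])
        if (dh[j, k] < 0.125) {
          p <- polar[j]
          donor_h[[p]] <- c(donor_h[[p]], hidx[k])
        }
      }
    }
    donors <- polar[!vapply(donor_h[polar], is.null, logical(1))]
  } else {
    message("no hydrogens present; applying donor-acceptor distance criterion only")
    donors <- polar
  }
  acceptors <- polar
  empty <- data.frame(chainD = character(), resD = integer(), donor = character(),
                      chainA = character(), resA = integer(), acceptor = character(),
                      dist = numeric(), angle = numeric())
  if (!length(donors) || !length(acceptors)) return(empty)

  dda <- cross_dist(xyz[donors, , drop = FALSE], xyz[acceptors, , drop = FALSE])
  hit <- which(dda < d_cut, arr.ind = TRUE)
  rows <- list()
  for (r in seq_len(nrow(hit))) {
    di <- donors[hit[r, 1]]; ai <- acceptors[hit[r, 2]]
    if (di == ai) next
    if (a$chain[di] == a$chain[ai] && a$resno[di] == a$resno[ai]) next
    ang <- NA_real_
    ok <- TRUE
    if (have_h) {
      v_a <- xyz[ai, ] - xyz[di, ]
      angs <- vapply(donor_h[[di]], function(h) {
        v_h <- xyz[h, ] - xyz[di, ]
        cosang <- sum(v_h * v_a) / sqrt(sum(v_h^2) * sum(v_a^2))
        acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      }, numeric(1))
      ang <- min(angs)
      ok <- ang < angle_cut
    }
    if (ok)
      rows[[length(rows) + 1L]] <- data.frame(
        chainD = a$chain[di], resD = a$resno[di], donor = a$atom[di],
        chainA = a$chain[ai], resA = a$resno[ai], acceptor = a$atom[ai],
        dist = dda[hit[r, 1], hit[r, 2]], angle = ang, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$chainD, out$resD, out$chainA, out$resA), , drop = FALSE]
}

#' Occurrence probability of an interaction over an ensemble
#'
#' Fraction of frames in which a detector reports a given pair, as used
#' for per-ion-pair stability probabilities over a trajectory.
#'
#' @param frames list of [structure3d()] frames.
#' @param pair named list of column values that must all match one row of
#'   the detector output (e.g. `list(resP = 37, resN = 246)`).
#' @param detector a detector function taking the structure as first
#'   argument (e.g. [detect_ion_pairs()]).
#' @param ... passed to the detector.
#' @return Probability in `[0, 1]`.
#' @export
pair_probability <- function(frames, pair, detector = detect_ion_pairs, ...) {
  if (!length(frames)) stop_invalid("need at least one frame")
  hits <- vapply(frames, function(f) {
    res <- detector(f, ...)
    if (!nrow(res)) return(FALSE)
    m <- rep(TRUE, nrow(res))
    for (nm in names(pair)) m <- m & (res[[nm]] == pair[[nm]])
    any(m)
  }, logical(1))
  mean(hits)
}

#' Charged fraction of a residue set
#'
#' Fraction of residues that are positively (Arg, Lys) and negatively
#' (Asp, Glu) charged. Histidine is counted as uncharged.
#'
#' @param residues character vector of 3-letter residue names.
#' @return Named numeric vector `c(positive = ..., negative = ...)`.
#' @export
charged_fraction <- function(residues) {
  residues <- toupper(residues)
  known <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")
  if (any(!residues %in% known))
    warning("unknown residue names counted as uncharged: ",
            paste(unique(setdiff(residues, known)), collapse = " "))
  c(positive = mean(residues %in% c("ARG", "LYS")),
    negative = mean(residues %in% c("ASP", "GLU")))
}
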