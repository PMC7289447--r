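# Toy two-chain complexes with planted interface geometry.
#
# Two extended pseudo-peptide chains run parallel to the x axis,
# `separation` nm apart along y. Two residues in the middle of each chain
# carry planted cross-chain features built exactly to specification:
# an Arg guanidine / Asp carboxylate ion pair whose group centres of mass
# sit `separation - 0.75` nm apart, and a Ser OG-H...OG hydrogen bond at
# donor-acceptor distance `separation - 0.90` nm with a stated
# hydrogen-donor-acceptor angle. At the default separation of 1.2 nm this
# gives a 0.45 nm ion pair and a 0.30 nm hydrogen bond; pulling the
# chains far apart removes every cross-chain feature.

res_backbone <- function(chain, resno, resname, origin, jitter) {
  off <- rbind(N = c(-0.15, 0.05, 0), CA = c(0, 0, 0), C = c(0.15, 0.05, 0),
               O = c(0.20, 0.15, 0), H = c(-0.15, -0.05, 0))
  pos <- sweep(off + jitter, 2, origin, "+")
  data.frame(chain = chain, resno = resno, resname = resname,
             atom = rownames(off),
             element = c("N", "C", "C", "O", "H"),
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             stringsAsFactors = FALSE)
}

# group atoms around an exact mass-weighted centre: the central atom sits at
# the COM and the satellite offsets of each element sum to zero
guanidine_atoms <- function(com) {
  off <- rbind(CZ = c(0, 0, 0), NE = c(0.13, 0, 0),
               NH1 = c(-0.065, 0, 0.113), NH2 = c(-0.065, 0, -0.113))
  pos <- sweep(off, 2, com, "+")
  data.frame(atom = rownames(off), element = c("C", "N", "N", "N"),
             x = pos[, 1], y = pos[, 2], z = pos[, 3], stringsAsFactors = FALSE)
}

carboxylate_atoms <- function(com, prefix = c("CG", "OD1", "OD2")) {
  off <- rbind(c(0, 0, 0), c(0, 0, 0.11), c(0, 0, -0.11))
  pos <- sweep(off, 2, com, "+")
  data.frame(atom = prefix, element = c("C", "O", "O"),
             x = pos[, 1], y = pos[, 2], z = pos[, 3], stringsAsFactors = FALSE)
}

#' Generate a toy two-chain complex with known interface geometry
#'
#' Builds a synthetic two-chain structure whose cross-chain contacts, ion
#' pair and hydrogen bond are planted exactly, and returns them as ground
#' truth for testing the geometric detectors.
#'
#' @param n_residues_per_chain residues per chain (>= 2).
#' @param seed RNG seed (controls filler residue identities and jitter).
#' @param separation distance between the chain axes (nm). The planted
#'   ion-pair COM distance is `separation - 0.75` and the planted
#'   donor-acceptor distance `separation - 0.90`.
#' @param hbond_angle_deg planted hydrogen-donor-acceptor angle (degrees).
#' @return A list with elements `structure` (a [structure3d()]) and
#'   `truth`: `planted_contacts` (cross-chain heavy-atom pairs < 0.5 nm),
#'   `planted_ion_pairs`, `planted_hbonds`.
#' @export
generate_toy_complex <- function(n_residues_per_chain, seed = 0L,
                                 separation = 1.2, hbond_angle_deg = 10) {
  n <- as.integer(n_residues_per_chain)
  if (n < 2) stop_invalid("n_residues_per_chain must be >= 2")
  # filler residues carry backbone atoms only, so none may need side-chain
  # groups (no charged or donor side chains)
  filler <- c("GLY", "ALA", "LEU", "VAL", "THR", "ASN", "PHE", "ILE", "MET")

  out <- with_seed(split_seed(seed, "toy_complex"), {
    rows <- list()
    pick <- function() filler[sample.int(length(filler), 1)]
    i_ion <- max(1L, n %/% 2L)      # planted ion-pair residues
    i_hb <- min(n, i_ion + 1L)      # planted H-bond residues
    for (chain in c("A", "B")) {
      ybase <- if (chain == "A") 0 else separation
      for (i in seq_len(n)) {
        resname <- if (i == i_ion) (if (chain == "A") "ARG" else "ASP")
                   else if (i == i_hb) "SER" else pick()
        jit <- matrix(stats::runif(15, -0.02, 0.02), 5, 3)
        origin <- c(0.5 * i, ybase, 0)
        rows[[length(rows) + 1L]] <- res_backbone(chain, i, resname, origin, jit)
        if (i == i_ion && chain == "A") {
          g <- guanidine_atoms(c(0.5 * i, 0.375, 0.15))
          rows[[length(rows) + 1L]] <- cbind(chain = chain, resno = i,
                                             resname = resname, g)
        }
        if (i == i_ion && chain == "B") {
          g <- carboxylate_atoms(c(0.5 * i, separation - 0.375, 0.15))
          rows[[length(rows) + 1L]] <- cbind(chain = chain, resno = i,
                                             resname = resname, g)
        }
        if (i == i_hb && chain == "A") {
          # Ser donor: OG plus hydroxyl H tilted off the donor-acceptor axis
          og <- c(0.5 * i, 0.45, 0.1)
          th <- hbond_angle_deg * pi / 180
          hg <- og + 0.1 * c(sin(th), cos(th), 0)
          rows[[length(rows) + 1L]] <-
            data.frame(chain = chain, resno = i, resname = resname,
                       atom = c("OG", "HG"), element = c("O", "H"),
                       x = c(og[1], hg[1]), y = c(og[2], hg[2]),
                       z = c(og[3], hg[3]), stringsAsFactors = FALSE)
        }
        if (i == i_hb && chain == "B") {
          og <- c(0.5 * i, separation - 0.45, 0.1)
          rows[[length(rows) + 1L]] <-
            data.frame(chain = chain, resno = i, resname = resname,
                       atom = "OG", element = "O",
                       x = og[1], y = og[2], z = og[3], stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
  s <- structure3d(out)

  # ground truth, enumerated from the construction itself
  a <- s$atoms
  heavyA <- which(a$chain == "A" & a$element != "H")
  heavyB <- which(a$chain == "B" & a$element != "H")
  d <- cross_dist(coords(s, heavyA), coords(s, heavyB))
  hit <- which(d < 0.5, arr.ind = TRUE)
  contacts <- if (nrow(hit) == 0) data.frame() else data.frame(
    chainA = "A", resA = a$resno[heavyA[hit[, 1]]], atomA = a$atom[heavyA[hit[, 1]]],
    chainB = "B", resB = a$resno[heavyB[hit[, 2]]], atomB = a$atom[heavyB[hit[, 2]]],
    dist = d[hit], stringsAsFactors = FALSE)
  if (nrow(contacts)) {
    contacts <- contacts[order(contacts$resA, contacts$atomA,
                               contacts$resB, contacts$atomB), ]
    rownames(contacts) <- NULL
  }

  i_ion <- max(1L, n %/% 2L); i_hb <- min(n, i_ion + 1L)
  com_d <- sqrt(sum((c(0.5 * i_ion, 0.375, 0.15) -
                     c(0.5 * i_ion, separation - 0.375, 0.15))^2))
  ion <- if (com_d < 0.5)
    data.frame(chainA = "A", resA = i_ion, groupA = "ARG",
               chainB = "B", resB = i_ion, groupB = "ASP",
               dist = com_d, stringsAsFactors = FALSE)
  else data.frame()

  da_d <- separation - 0.90
  hb <- if (da_d < 0.35 && hbond_angle_deg < 30)
    data.frame(chainD = "A", resD = i_hb, donor = "OG",
               chainA = "B", resA = i_hb, acceptor = "OG",
               dist = da_d, angle = hbond_angle_deg, stringsAsFactors = FALSE)
  else data.frame()

  list(structure = s,
       truth = list(planted_contacts = contacts,
                    planted_ion_pairs = ion,
                    planted_hbonds = hb))
}

#' Write a toy-complex ground truth as JSON
#'
#' @param truth the `truth` element returned by [generate_toy_complex()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# all-pairs Euclidean distances between two coordinate sets (rows)
cross_dist <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb)
  if (na == 0 || nb == 0) return(matrix(numeric(0), na, nb))
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
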