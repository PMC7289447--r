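#' Molecular structure container (coordinates in nm)
#'
#' Atoms of a (possibly multi-chain) molecular model. Internally all
#' coordinates are stored in nanometres; PDB I/O converts from/to the
#' Angstrom convention of the format.
#'
#' @param atoms data.frame with columns `chain` (character), `resno`
#'   (integer), `resname` (3-letter code), `atom` (atom name), `element`
#'   (element symbol) and `x`, `y`, `z` (nm).
#' @param model model id (integer, default 1).
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, model = 1L) {
  req <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(req %in% names(atoms)))
    stop_invalid("`atoms` must have columns ", paste(req, collapse = ", "))
  atoms <- atoms[req]
  atoms$resno <- as.integer(atoms$resno)
  if (nrow(atoms)) {
    if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
      stop_invalid("all coordinates must be finite")
    key <- paste(atoms$chain, atoms$resno, atoms$atom)
    if (anyDuplicated(key))
      stop_invalid("duplicate (chain, resno, atom) entries: ",
                   paste(head(key[duplicated(key)], 3), collapse = "; "))
  }
  structure(list(atoms = atoms, model = as.integer(model)), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure3d: %d atoms, %d chains (%s), %d residues [model %d]\n",
              nrow(a), length(unique(a$chain)),
              paste(sort(unique(a$chain)), collapse = ","),
              length(unique(paste(a$chain, a$resno))), x$model))
  invisible(x)
}

coords <- function(s, idx = NULL) {
  m <- as.matrix(s$atoms[c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP4", "SOL", "SPC", "DOD")

# infer an element symbol from a PDB atom name ("1HB" -> H, "OD1" -> O, ...)
element_from_name <- function(name) {
  core <- sub("^[0-9']+", "", trimws(name))
  toupper(substr(core, 1, 1))
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records via [bio3d::read.pdb()], converts
#' coordinates to nm, resolves alternate locations to the highest
#' occupancy, and drops waters by default.
#'
#' @param path PDB file path.
#' @param keep_water keep water molecules (default `FALSE`).
#' @param model which model of a multi-model file (default 1).
#' @return A [structure3d()] object.
#' @seealso [read_pdb_frames()] for multi-model files as a frame list.
#' @export
read_pdb <- function(path, keep_water = FALSE, model = 1L) {
  frames <- read_pdb_frames(path, keep_water = keep_water)
  if (length(frames) == 0) return(frames)
  if (model > length(frames)) stop_invalid("model ", model, " not present (",
                                           length(frames), " models)")
  frames[[model]]
}

#' @rdname read_pdb
#' @export
read_pdb_frames <- function(path, keep_water = FALSE) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  check_pdb_coords(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  a <- pdb$atom
  if (nrow(a) == 0) {
    warning("no ATOM records in ", path)
    empty <- structure3d(data.frame(chain = character(), resno = integer(),
                                    resname = character(), atom = character(),
                                    element = character(),
                                    x = numeric(), y = numeric(), z = numeric()))
    return(list(empty))
  }
  keep <- rep(TRUE, nrow(a))
  if (!keep_water) keep <- keep & !(a$resid %in% WATER_RESNAMES)
  # alternate locations: keep the highest-occupancy copy of each atom
  alt <- !is.na(a$alt) & a$alt != "" & a$alt != " "
  if (any(alt)) {
    occ <- ifelse(is.na(a$o), 1, a$o)
    key <- paste(a$chain, a$resno, a$insert, a$elety)
    ord <- order(key, -occ)
    dup <- duplicated(key[ord])
    drop_idx <- ord[dup]
    keep[drop_idx] <- FALSE
  }
  a <- a[keep, , drop = FALSE]
  sel_xyz <- as.vector(t(cbind(3 * (which(keep)) - 2, 3 * which(keep) - 1,
                               3 * which(keep))))
  elem <- a$elesy
  miss <- is.na(elem) | trimws(elem) == ""
  elem[miss] <- element_from_name(a$elety[miss])
  n_model <- nrow(pdb$xyz)
  lapply(seq_len(n_model), function(m) {
    xyz <- matrix(pdb$xyz[m, sel_xyz], ncol = 3, byrow = TRUE) / 10  # A -> nm
    structure3d(data.frame(chain = as.character(a$chain), resno = a$resno,
                           resname = a$resid, atom = a$elety,
                           element = toupper(trimws(elem)),
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                           stringsAsFactors = FALSE),
                model = m)
  })
}

# cheap pre-scan so malformed coordinate fields are reported with a line number
check_pdb_coords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    fld <- substring(lines[i], c(31, 39, 47), c(38, 46, 54))
    if (anyNA(suppressWarnings(as.numeric(fld))))
      stop_invalid("malformed coordinate field at line ", i, " of ", path)
  }
  invisible(TRUE)
}

#' Write a structure (or frames) as PDB
#'
#' Coordinates are emitted in Angstrom. A list of frames is written as a
#' multi-model PDB.
#'
#' @param s a [structure3d()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  frames <- if (inherits(s, "structure3d")) list(s) else s
  stopifnot(all(vapply(frames, inherits, logical(1), "structure3d")))
  a <- frames[[1]]$atoms
  xyz <- do.call(rbind, lapply(frames, function(f) {
    as.vector(t(coords(f))) * 10  # nm -> A
  }))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resname,
                   chain = a$chain, elety = a$atom, elesy = a$element,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}
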