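#' Amino-acid alignment container
#'
#' A thin S3 wrapper around a character matrix (one row per record, one
#' column per alignment position) over the 20-letter amino-acid alphabet
#' plus the gap character `-`. Column metadata (which partner family a
#' column came from and its original column index) is carried in the
#' `col_meta` attribute and is filled in by [pair_orthologs()].
#'
#' @param x character matrix of single residues (rows named by record id),
#'   or a named character vector of equal-length sequence strings.
#' @param col_meta optional data.frame with columns `family` and `orig_col`,
#'   one row per alignment column.
#' @return An object of class `aa_alignment`.
#' @export
aa_alignment <- function(x, col_meta = NULL) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop_invalid("sequence vector must be named by record id")
    lens <- nchar(x)
    if (length(unique(lens)) > 1L) stop_invalid("sequences must have equal length")
    m <- if (lens[1] == 0L) matrix(character(0), nrow = length(x), ncol = 0L)
         else do.call(rbind, strsplit(x, ""))
    rownames(m) <- names(x)
    x <- m
  }
  if (!is.matrix(x) || !is.character(x)) stop_invalid("`x` must be a character matrix")
  if (is.null(rownames(x))) stop_invalid("alignment rows must be named by record id")
  if (anyDuplicated(rownames(x))) stop_invalid("record ids must be unique")
  x[] <- toupper(x)
  bad <- setdiff(unique(as.vector(x)), c(AA_ALPHABET, GAP_CHAR, "X"))
  if (length(bad)) stop_invalid("invalid alignment characters: ", paste(bad, collapse = " "))
  if (!is.null(col_meta)) {
    stopifnot(is.data.frame(col_meta), nrow(col_meta) == ncol(x))
  }
  structure(x, col_meta = col_meta, class = c("aa_alignment", "matrix", "array"))
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("aa_alignment: %d sequences x %d columns\n", nrow(x), ncol(x)))
  n <- min(5L, nrow(x))
  for (i in seq_len(n)) {
    s <- paste(x[i, seq_len(min(60L, ncol(x)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", rownames(x)[i], s, if (ncol(x) > 60) "..." else ""))
  }
  if (nrow(x) > n) cat(sprintf("  ... %d more\n", nrow(x) - n))
  invisible(x)
}

#' Read / write an aligned FASTA file
#'
#' Wrappers over [bio3d::read.fasta()] / [bio3d::write.fasta()] returning
#' an [aa_alignment()].
#'
#' @param path file path.
#' @return `read_fasta`: an `aa_alignment`; `write_fasta`: `path`, invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  fa <- bio3d::read.fasta(path, rm.dup = FALSE)
  m <- fa$ali
  rownames(m) <- fa$id
  m[m == "."] <- GAP_CHAR
  aa_alignment(m)
}

#' @param aln an `aa_alignment`.
#' @rdname read_fasta
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "aa_alignment"))
  bio3d::write.fasta(seqs = unclass(aln), ids = rownames(aln), file = path)
  invisible(path)
}

# gap pattern per column (logical matrix helper)
is_gap <- function(aln) unclass(aln) == GAP_CHAR | unclass(aln) == "X"
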