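# End-to-end interface coevolution analysis: pair two ortholog families
# on one tree, map structural interface residues to alignment columns,
# scan all cross-interface column pairs with the coevolution test, and
# calibrate the dAIC significance threshold by simulation under the
# independent model.

#' Pair two ortholog alignments by species
#'
#' Concatenates one sequence per species from each family; species
#' missing from either family are dropped with a message. Record ids are
#' reduced to species keys with `species_regex` (first capture group),
#' or used verbatim when `NULL`.
#'
#' @param msaA,msaB [aa_alignment()] objects for the two families.
#' @param species_regex optional regex whose first capture group
#'   extracts the species key from a record id.
#' @return An `aa_alignment` of the paired records (ids = species keys)
#'   with per-column provenance in `col_meta` (`family` = "A"/"B",
#'   `orig_col`) and the A-block width in attribute `block_A`.
#' @export
pair_orthologs <- function(msaA, msaB, species_regex = NULL) {
  key <- function(ids) {
    if (is.null(species_regex)) return(ids)
    out <- sub(paste0(".*", species_regex, ".*"), "\\1", ids)
    ifelse(grepl(species_regex, ids), out, ids)
  }
  ka <- key(rownames(msaA)); kb <- key(rownames(msaB))
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stop_invalid("duplicated species id within one family: pairing is ambiguous")
  common <- intersect(ka, kb)
  if (!length(common)) stop_invalid("no overlapping species between the families")
  dropped <- (length(ka) - length(common)) + (length(kb) - length(common))
  if (dropped > 0) message(dropped, " unpaired record(s) dropped")
  a <- unclass(msaA)[match(common, ka), , drop = FALSE]
  b <- unclass(msaB)[match(common, kb), , drop = FALSE]
  m <- cbind(a, b)
  rownames(m) <- common
  meta <- data.frame(
    family = rep(c("A", "B"), c(ncol(a), ncol(b))),
    orig_col = c(seq_len(ncol(a)), seq_len(ncol(b))))
  out <- aa_alignment(m, col_meta = meta)
  attr(out, "block_A") <- ncol(a)
  out
}

#' Map structure residue numbers to alignment columns
#'
#' Gap-aware mapping: residue `i` of the reference sequence corresponds
#' to the column holding its `i`-th non-gap character.
#'
#' @param msa an [aa_alignment()].
#' @param ref_id record id of the reference sequence.
#' @param resnos integer residue numbers (1-based in the ungapped
#'   reference).
#' @return data.frame with `resno`, `column` (`NA` when unmappable) and
#'   `reason` for unmapped residues.
#' @export
map_interface_to_columns <- function(msa, ref_id, resnos) {
  if (!ref_id %in% rownames(msa)) stop_invalid("reference record not found: ", ref_id)
  ref <- unclass(msa)[ref_id, ]
  res_cols <- which(!(ref %in% c(GAP_CHAR, "X")))
  col <- rep(NA_integer_, length(resnos))
  reason <- rep(NA_character_, length(resnos))
  for (i in seq_along(resnos)) {
    r <- resnos[i]
    if (r < 1 || r > length(res_cols)) reason[i] <- "beyond reference length"
    else col[i] <- res_cols[r]
  }
  data.frame(resno = as.integer(resnos), column = col, reason = reason)
}

#' Scan all cross-interface column pairs for coevolution
#'
#' Fits the independent and coevolution models to every pair
#' `(a in colsA, b in colsB)` and records the dAIC. Pairs with fewer
#' than 4 species ungapped in both columns are skipped with a reason.
#'
#' @param tree rooted `phylo`; tips must match the paired alignment ids.
#' @param paired alignment from [pair_orthologs()] (or any
#'   `aa_alignment` whose rows are tree tips).
#' @param colsA,colsB alignment column indices of the two interface
#'   sides.
#' @return A `coev_scan`: list with `table`
#'   (`colA,colB,logL_ind,logL_coev,AIC_ind,AIC_coev,dAIC,s,d,n_ungapped`),
#'   `skipped`, and an unset `threshold`/`calls`.
#' @export
scan_interface_pairs <- function(tree, paired, colsA, colsB) {
  m <- unclass(paired)
  meta <- attr(paired, "col_meta")
  if (!is.null(meta)) {
    if (any(meta$family[colsA] != "A")) stop_invalid("colsA must lie in the A block")
    if (any(meta$family[colsB] != "B")) stop_invalid("colsB must lie in the B block")
  }
  rows <- list(); skipped <- list()
  for (a in colsA) for (b in colsB) {
    col1 <- setNames(m[, a], rownames(m))
    col2 <- setNames(m[, b], rownames(m))
    n_ok <- sum(!(col1 %in% c(GAP_CHAR, "X")) & !(col2 %in% c(GAP_CHAR, "X")))
    if (n_ok < 4) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        colA = a, colB = b, reason = sprintf("only %d ungapped pairs", n_ok))
      next
    }
    ind <- fit_independent_pair(tree, col1, col2)
    cv <- fit_coev_pair(tree, col1, col2)
    rows[[length(rows) + 1L]] <- data.frame(
      colA = a, colB = b, logL_ind = ind$logL, logL_coev = cv$logL,
      AIC_ind = ind$AIC, AIC_coev = cv$AIC, dAIC = delta_aic(ind, cv),
      s = unname(cv$parameters["s"]), d = unname(cv$parameters["d"]),
      n_ungapped = n_ok, converged = cv$converged && ind$converged)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(colA = integer(), colB = integer(), logL_ind = numeric(),
               logL_coev = numeric(), AIC_ind = numeric(), AIC_coev = numeric(),
               dAIC = numeric(), s = numeric(), d = numeric(),
               n_ungapped = integer(), converged = logical())
  structure(list(table = tab,
                 skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
                 threshold = NA_real_, calls = NULL),
            class = "coev_scan")
}

#' @export
print.coev_scan <- function(x, ...) {
  cat(sprintf("coev_scan: %d column pairs (max dAIC %.3f)%s\n", nrow(x$table),
              if (nrow(x$table)) max(x$table$dAIC) else NA,
              if (is.na(x$threshold)) ", threshold unset"
              else sprintf(", threshold %.3f, %d call(s)", x$threshold,
                           nrow(x$calls))))
  if (!is.na(x$threshold) && !is.null(x$calls) && nrow(x$calls))
    cat(sprintf("  called: %d position pairs over %d distinct positions\n",
                nrow(x$calls),
                length(unique(c(paste0("A", x$calls$colA),
                                paste0("B", x$calls$colB))))))
  invisible(x)
}

#' Calibrate the null dAIC threshold by simulation
#'
#' Simulates `n_replicates` alignments of `n_cols` columns under the
#' independent model on the same tree, computes the dAIC for every pair
#' of simulated positions, and returns the requested percentile
#' (linear-interpolation definition, `quantile` type 7) of the pooled
#' null distribution.
#'
#' @param tree rooted `phylo`.
#' @param n_cols columns per simulated alignment.
#' @param n_replicates number of null alignments (>= 50 recommended;
#'   fewer draws a warning).
#' @param percentile percentile of the pooled null dAIC (default 99,
#'   i.e. a p < 0.01 acceptance level).
#' @param seed RNG seed.
#' @param col_rates per-column rates of the null generator (default
#'   0.05).
#' @return The threshold, with the pooled null dAIC values in attribute
#'   `null_daic`.
#' @export
calibrate_null_threshold <- function(tree, n_cols = 2L, n_replicates = 200L,
                                     percentile = 99, seed = 0L,
                                     col_rates = 0.05) {
  if (n_replicates < 1) stop_invalid("n_replicates must be >= 1")
  if (n_replicates < 50) warning("fewer than 50 replicates: threshold will be noisy")
  vals <- numeric(0)
  for (rep_i in seq_len(n_replicates)) {
    aln <- simulate_alignment_independent(tree, n_cols, col_rates,
                                          seed = split_seed(seed, paste0("null", rep_i)))
    m <- unclass(aln)
    for (a in seq_len(n_cols - 1)) for (b in seq((a + 1), n_cols)) {
      col1 <- setNames(m[, a], rownames(m)); col2 <- setNames(m[, b], rownames(m))
      ok <- tryCatch({
        ind <- fit_independent_pair(tree, col1, col2)
        cv <- fit_coev_pair(tree, col1, col2)
        delta_aic(ind, cv)
      }, error = function(e) NA_real_)
      if (is.finite(ok)) vals <- c(vals, ok)
    }
  }
  thr <- unname(quantile(vals, percentile / 100, type = 7, names = FALSE))
  attr(thr, "null_daic") <- vals
  thr
}

#' Call coevolving pairs against a threshold
#'
#' Pairs with `dAIC >= threshold` are called (inclusive at the
#' boundary).
#'
#' @param scan a `coev_scan` from [scan_interface_pairs()].
#' @param threshold dAIC threshold, e.g. from
#'   [calibrate_null_threshold()].
#' @return The scan with `threshold` set and `calls` filled in.
#' @export
call_coevolving <- function(scan, threshold) {
  stopifnot(inherits(scan, "coev_scan"))
  if (!nrow(scan$table)) stop_invalid("scan table is empty")
  scan$threshold <- as.numeric(threshold)
  scan$calls <- scan$table[scan$table$dAIC >= scan$threshold, , drop = FALSE]
  scan
}

#' Per-column amino-acid frequencies and charge summary
#'
#' Frequency matrix over non-gap residues for the requested columns
#' (sequence-logo heights) plus the charged fractions of each column.
#'
#' @param msa an [aa_alignment()].
#' @param columns column indices.
#' @return list with `freq` (20 x length(columns) matrix, columns sum to
#'   1; all-gap columns are zero and flagged), `charge` (data.frame of
#'   positive/negative fractions per column) and `all_gap` (logical).
#' @export
column_frequency_logo <- function(msa, columns) {
  m <- unclass(msa)
  if (any(columns < 1 | columns > ncol(m))) stop_invalid("column index out of range")
  freq <- matrix(0, length(AA_ALPHABET), length(columns),
                 dimnames = list(AA_ALPHABET, columns))
  pos_set <- c("R", "K"); neg_set <- c("D", "E")
  charge <- data.frame(column = columns, positive = 0, negative = 0)
  all_gap <- logical(length(columns))
  for (i in seq_along(columns)) {
    col <- m[, columns[i]]
    res <- col[!(col %in% c(GAP_CHAR, "X"))]
    if (!length(res)) { all_gap[i] <- TRUE; next }
    tab <- table(factor(res, levels = AA_ALPHABET))
    freq[, i] <- as.numeric(tab) / length(res)
    charge$positive[i] <- mean(res %in% pos_set)
    charge$negative[i] <- mean(res %in% neg_set)
  }
  if (any(all_gap)) warning("all-gap column(s): ",
                            paste(columns[all_gap], collapse = " "))
  list(freq = freq, charge = charge, all_gap = all_gap)
}
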