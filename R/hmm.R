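# Profile-HMM confidence filter for alignment columns.
#
# A Krogh-style profile HMM (match / insert / delete states, +1
# pseudocounts) is built from the alignment itself: match states are the
# columns with less than 50% gaps. The forward-backward algorithm (in
# log space) then gives, for every residue of every sequence, the
# posterior probability of the state that the alignment assigns it to;
# residues below the threshold are replaced by gaps.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

build_profile_hmm <- function(aln) {
  m <- unclass(aln)
  gapf <- colMeans(is_gap(aln))
  match_cols <- which(gapf < 0.5)
  k <- length(match_cols)
  if (k == 0) stop_invalid("alignment has no match columns (all columns >= 50% gaps)")
  nA <- length(AA_ALPHABET)

  # emissions
  eM <- matrix(1, k, nA, dimnames = list(NULL, AA_ALPHABET))  # +1 pseudocount
  for (j in seq_len(k)) {
    tab <- table(factor(m[, match_cols[j]], levels = AA_ALPHABET))
    eM[j, ] <- eM[j, ] + as.numeric(tab)
  }
  eM <- eM / rowSums(eM)
  bg <- table(factor(m[!is_gap(aln)], levels = AA_ALPHABET)) + 1
  eI <- as.numeric(bg / sum(bg))

  # transition counts from each sequence's deterministic state path
  snames <- c("M", "I", "D")
  counts <- array(1, dim = c(k + 1, 3, 3), dimnames = list(NULL, snames, snames))
  col_match <- match(seq_len(ncol(m)), match_cols)            # NA for insert cols
  n_match_before <- cumsum(seq_len(ncol(m)) %in% match_cols)  # index j at column
  for (r in seq_len(nrow(m))) {
    prev <- c(1L, 1L)  # state M_0 (begin): (level j + 1, type index)
    for (cc in seq_len(ncol(m))) {
      gap <- is_gap(aln)[r, cc]
      if (!is.na(col_match[cc])) {
        cur <- c(col_match[cc] + 1L, if (gap) 3L else 1L)      # M_j or D_j
      } else if (!gap) {
        cur <- c(n_match_before[cc] + 1L, 2L)                  # I_j
      } else next
      counts[prev[1], prev[2], cur[2]] <- counts[prev[1], prev[2], cur[2]] + 1
      prev <- cur
    }
    counts[prev[1], prev[2], 1] <- counts[prev[1], prev[2], 1] + 1  # -> End (as M)
  }
  trans <- counts
  for (j in seq_len(k + 1)) for (a in 1:3)
    trans[j, a, ] <- counts[j, a, ] / sum(counts[j, a, ])

  list(k = k, match_cols = match_cols, eM = log(eM), eI = log(eI),
       lt = log(trans))
}

# log-space forward/backward over one ungapped residue sequence
# returns log posterior matrices for M and I state occupancies
profile_fb <- function(hmm, res_idx) {
  k <- hmm$k; L <- length(res_idx)
  lt <- hmm$lt  # [level j+1, from, to]; level j covers transitions out of *_j
  NEG <- -Inf
  fM <- matrix(NEG, L + 1, k + 1); fI <- matrix(NEG, L + 1, k + 1)
  fD <- matrix(NEG, L + 1, k + 1)
  fM[1, 1] <- 0  # begin state M_0, zero symbols emitted; column j+1 = level j
  # delete chain at i = 0
  for (j in seq_len(k)) {
    from <- if (j == 1) fM[1, 1] + lt[1, 1, 3] else fD[1, j] + lt[j, 3, 3]
    fD[1, j + 1] <- from
  }
  for (i in seq_len(L)) {
    a <- res_idx[i]
    for (j in seq_len(k)) {
      fM[i + 1, j + 1] <- hmm$eM[j, a] + logsumexp(c(
        fM[i, j] + lt[j, 1, 1], fI[i, j] + lt[j, 2, 1], fD[i, j] + lt[j, 3, 1]))
    }
    for (j in 0:k) {
      fI[i + 1, j + 1] <- hmm$eI[a] + logsumexp(c(
        fM[i, j + 1] + lt[j + 1, 1, 2], fI[i, j + 1] + lt[j + 1, 2, 2],
        fD[i, j + 1] + lt[j + 1, 3, 2]))
    }
    for (j in seq_len(k)) {
      from <- c(fM[i + 1, j] + lt[j, 1, 3], fI[i + 1, j] + lt[j, 2, 3],
                if (j > 1) fD[i + 1, j] + lt[j, 3, 3] else NEG)
      fD[i + 1, j + 1] <- logsumexp(from)
    }
  }
  logP <- logsumexp(c(fM[L + 1, k + 1] + lt[k + 1, 1, 1],
                      fI[L + 1, k + 1] + lt[k + 1, 2, 1],
                      fD[L + 1, k + 1] + lt[k + 1, 3, 1]))

  bM <- matrix(NEG, L + 1, k + 1); bI <- matrix(NEG, L + 1, k + 1)
  bD <- matrix(NEG, L + 1, k + 1)
  bM[L + 1, k + 1] <- lt[k + 1, 1, 1]
  bI[L + 1, k + 1] <- lt[k + 1, 2, 1]
  bD[L + 1, k + 1] <- lt[k + 1, 3, 1]
  for (j in k:1) {  # delete chain at i = L
    bD[L + 1, j] <- lt[j, 3, 3] + bD[L + 1, j + 1]
    bM[L + 1, j] <- lt[j, 1, 3] + bD[L + 1, j + 1]
    bI[L + 1, j] <- lt[j, 2, 3] + bD[L + 1, j + 1]
  }
  for (i in L:1) {
    a <- res_idx[i]
    for (j in (k + 1):1) {
      toM <- if (j <= k) hmm$eM[j, a] + bM[i + 1, j + 1] else NEG
      toI <- hmm$eI[a] + bI[i + 1, j]
      toD <- if (j <= k) bD[i, j + 1] else NEG
      bM[i, j] <- logsumexp(c(lt[j, 1, 1] + toM, lt[j, 1, 2] + toI,
                              lt[j, 1, 3] + toD))
      bI[i, j] <- logsumexp(c(lt[j, 2, 1] + toM, lt[j, 2, 2] + toI,
                              lt[j, 2, 3] + toD))
      bD[i, j] <- logsumexp(c(lt[j, 3, 1] + toM, lt[j, 3, 2] + toI,
                              lt[j, 3, 3] + toD))
    }
  }
  list(postM = fM + bM - logP, postI = fI + bI - logP, logP = logP)
}

#' Mask low-confidence alignment positions with a profile HMM
#'
#' Builds a profile HMM from the alignment (match columns are those with
#' under 50% gaps; +1 pseudocounts) and computes, by the
#' forward-backward algorithm, the posterior probability that each
#' residue occupies the state its alignment column assigns to it.
#' Residues with posterior below `pp_threshold` are replaced by gaps.
#'
#' @param msa an [aa_alignment()] with >= 2 sequences.
#' @param pp_threshold posterior-probability threshold (default 0.7).
#' @return The masked `aa_alignment`, with the posterior matrix in
#'   attribute `pp` (`NA` at gaps).
#' @export
hmm_posterior_mask <- function(msa, pp_threshold = 0.7) {
  stopifnot(inherits(msa, "aa_alignment"))
  if (nrow(msa) < 2) stop_invalid("need >= 2 sequences")
  hmm <- build_profile_hmm(msa)
  m <- unclass(msa)
  gaps <- is_gap(msa)
  ppm <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  col_match <- match(seq_len(ncol(m)), hmm$match_cols)
  n_match_before <- cumsum(seq_len(ncol(m)) %in% hmm$match_cols)

  for (r in seq_len(nrow(m))) {
    res_cols <- which(!gaps[r, ])
    if (!length(res_cols)) next
    res_idx <- match(m[r, res_cols], AA_ALPHABET)
    fb <- profile_fb(hmm, res_idx)
    for (q in seq_along(res_cols)) {
      cc <- res_cols[q]
      ppm[r, cc] <- if (!is.na(col_match[cc]))
        exp(fb$postM[q + 1, col_match[cc] + 1])
      else
        exp(fb$postI[q + 1, n_match_before[cc] + 1])
    }
  }

  masked <- m
  masked[!is.na(ppm) & ppm < pp_threshold] <- GAP_CHAR
  out <- aa_alignment(masked, col_meta = attr(msa, "col_meta"))
  attr(out, "pp") <- ppm
  out
}
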