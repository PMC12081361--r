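# Primer binding-site conservation analysis.
#
# From an anchored alignment: derive a consensus, locate each primer's
# binding site on it, tally per-primer-position residue counts across all
# rows, convert to sequence-logo information content (R = 2 - H bits) and
# flag 3'-end mismatch risk.  Reverse primers are handled so the reported
# matrices always read 5'->3' in primer orientation.

#' Consensus sequence of an alignment
#'
#' Per column: the majority residue over non-gap counts; ties are encoded
#' as the IUPAC code of the tied set; columns where gaps are the strict
#' majority are emitted as `-` (and skipped by site location).
#'
#' @param msa Alignment matrix over `{A,C,G,T,-}`.
#' @param source Optional genus/community label carried as an attribute.
#' @return Character scalar of class `consensus_seq`, one symbol per
#'   column.
#' @export
consensus <- function(msa, source = NA_character_) {
  stopifnot(nrow(msa) >= 1L)
  lv <- c("A", "C", "G", "T")
  bits <- c(1L, 2L, 4L, 8L)
  syms <- apply(msa, 2L, function(col) {
    counts <- tabulate(match(col, lv), 4L)
    if (sum(counts) * 2L < length(col)) return("-")
    top <- which(counts == max(counts) & counts > 0L)
    .BITS_TO_SYMBOL[sum(bits[top])]
  })
  structure(paste(syms, collapse = ""), class = "consensus_seq",
            source = source)
}

#' Locate a primer's binding site on a consensus
#'
#' Scans every window of the gap-free consensus and returns the one
#' minimising mismatches, where a position mismatches when the consensus
#' symbol's expansion is not a subset of the primer symbol's expansion
#' (same semantics as the PCR engine).  Ties resolve leftmost.  Reverse
#' primers should be passed reverse-complemented.
#'
#' @param primer IUPAC primer string, 5'->3' on the sense strand.
#' @param consensus A `consensus_seq` (or plain string, possibly
#'   containing gaps, which are skipped).
#' @param max_mm Maximum mismatches for a reportable site.
#' @return List with `site_start` (1-based frame column of the site's
#'   first residue) and `mismatch_count`, or `NULL` when the best window
#'   exceeds `max_mm`.
#' @export
locate_site <- function(primer, consensus, max_mm = 3L) {
  cons_chars <- strsplit(unclass(consensus), "", fixed = TRUE)[[1]]
  residue_cols <- which(cons_chars != "-")
  if (length(residue_cols) < nchar(primer)) return(NULL)
  p <- iupac_bits(primer, "primer")
  cbits <- iupac_bits(paste(cons_chars[residue_cols], collapse = ""),
                      "consensus")
  k <- length(p)
  nwin <- length(cbits) - k + 1L
  mm <- integer(nwin)
  for (i in seq_len(k)) {
    mm <- mm + (bitwAnd(cbits[i:(i + nwin - 1L)], bitwNot(p[i])) != 0L)
  }
  best <- which.min(mm)
  if (mm[best] > max_mm) return(NULL)
  list(site_start = residue_cols[best], mismatch_count = mm[best])
}

#' Per-position residue counts and information content at a binding site
#'
#' Counts are tallied column-wise over all alignment rows (gaps
#' excluded).  For `orientation = "reverse"` the residues are complemented
#' and the positions reversed, so rows of the matrix always follow the
#' primer 5'->3' with the 3' end last.
#'
#' @param msa Alignment matrix.
#' @param site_start 1-based frame column of the binding site's first
#'   base (sense-strand orientation).
#' @param primer The primer, 5'->3' on its own strand.
#' @param orientation `"forward"` or `"reverse"`.
#' @return Object of class `binding_site_matrix`: list with `primer`,
#'   `site_start`, `orientation`, `counts` (positions x A/C/G/T),
#'   `n_eff`, `low_support` (positions with under half the rows bearing a
#'   residue) and `info` (bits per position).
#' @export
site_matrix <- function(msa, site_start, primer,
                        orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  k <- nchar(primer)
  if (site_start < 1L || site_start + k - 1L > ncol(msa)) {
    stop("binding site falls outside the alignment frame", call. = FALSE)
  }
  lv <- c("A", "C", "G", "T")
  sub <- msa[, site_start:(site_start + k - 1L), drop = FALSE]
  counts <- t(apply(sub, 2L, function(col) tabulate(match(col, lv), 4L)))
  colnames(counts) <- lv
  if (orientation == "reverse") {
    # complement residues and flip position order -> primer 5'->3'
    counts <- counts[rev(seq_len(nrow(counts))), c("T", "G", "C", "A"),
                     drop = FALSE]
    colnames(counts) <- lv
  }
  rownames(counts) <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  n_eff <- rowSums(counts)
  structure(list(primer = toupper(primer), site_start = site_start,
                 orientation = orientation, counts = counts,
                 n_eff = as.integer(n_eff),
                 low_support = n_eff < nrow(msa) / 2,
                 info = information_content(counts)),
            class = "binding_site_matrix")
}

#' @export
print.binding_site_matrix <- function(x, ...) {
  cat(sprintf("binding_site_matrix: %s primer %s at frame column %d\n",
              x$orientation, x$primer, x$site_start))
  invisible(x)
}

#' Sequence-logo information content per position
#'
#' \eqn{R_i = 2 - H_i} bits, where \eqn{H_i} is the Shannon entropy of
#' position i's residue counts: 2 bits for a perfectly conserved
#' position, 0 for equal probability of all four nucleotides.  The
#' optional small-sample correction subtracts \eqn{3 / (2 \ln 2 \, n)};
#' values are clamped at 0.
#'
#' @param counts Matrix (positions x A/C/G/T) or single count vector.
#' @param correction `"none"` (matches a plain 0-2 bit logo scale) or
#'   `"small_sample"`.
#' @return Numeric vector of bits per position.
#' @export
information_content <- function(counts, correction = c("none",
                                                       "small_sample")) {
  correction <- match.arg(correction)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  vapply(seq_len(nrow(counts)), function(i) {
    n <- sum(counts[i, ])
    r <- 2 - shannon_entropy(counts[i, ])
    if (correction == "small_sample") r <- r - 3 / (2 * log(2) * n)
    max(0, r)
  }, numeric(1))
}

#' Per-position primer incompatibility and 3'-end risk flag
#'
#' For each primer position, the fraction of non-gap residues that fall
#' outside the primer symbol's IUPAC expansion.  The 3' flag is raised
#' when any of the last `three_prime_k` positions exceeds `flag_thr`,
#' reflecting that even a single mismatch near a primer's 3' end can
#' strongly reduce amplification efficiency.
#'
#' @param primer IUPAC primer string (5'->3', matching the matrix rows).
#' @param matrix A `binding_site_matrix` for that primer.
#' @param three_prime_k Number of 3'-terminal positions inspected.
#' @param flag_thr Incompatible-fraction threshold for the flag.
#' @return List with `incompatible_fraction` (per position),
#'   `three_prime_flag` and `flagged_positions` (1-based primer
#'   positions among the last `three_prime_k` exceeding the threshold).
#' @export
mismatch_report <- function(primer, matrix, three_prime_k = 4L,
                            flag_thr = 0.1) {
  p <- iupac_bits(primer, "primer")
  if (length(p) != nrow(matrix$counts)) {
    stop("matrix is not aligned to this primer", call. = FALSE)
  }
  base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  frac <- vapply(seq_along(p), function(i) {
    cts <- matrix$counts[i, ]
    tot <- sum(cts)
    if (tot == 0L) return(NA_real_)
    bad <- bitwAnd(base_bits[colnames(matrix$counts)], bitwNot(p[i])) != 0L
    sum(cts[bad]) / tot
  }, numeric(1))
  tail_idx <- seq(max(1L, length(p) - three_prime_k + 1L), length(p))
  flagged <- tail_idx[!is.na(frac[tail_idx]) & frac[tail_idx] > flag_thr]
  list(incompatible_fraction = frac,
       three_prime_flag = length(flagged) > 0L,
       flagged_positions = flagged)
}
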