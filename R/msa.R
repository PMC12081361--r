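# Multiple sequence alignment: a built-in center-star aligner so the
# pipeline runs with no external dependency, plus a pluggable external
# aligner (e.g. MAFFT) invoked through a temporary FASTA round trip.
#
# Alignments are represented as a character matrix (rows = records,
# columns = alignment columns) over {A,C,G,T,-}; ambiguity codes are
# normalised to gap on construction since they carry no single-residue
# evidence for profiling.

normalize_aln_chars <- function(chars) {
  chars[!(chars %in% c("A", "C", "G", "T", "-"))] <- "-"
  chars
}

aln_matrix_from_strings <- function(seqs, ids) {
  chars <- strsplit(toupper(seqs), "", fixed = TRUE)
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L) {
    stop("aligned rows have unequal lengths", call. = FALSE)
  }
  m <- do.call(rbind, chars)
  m <- matrix(normalize_aln_chars(m), nrow = nrow(m))
  rownames(m) <- ids
  m
}

#' Build a multiple sequence alignment
#'
#' The built-in method is a center-star alignment: the star is the record
#' minimising total pairwise distance (Hamming when all sequences share a
#' length, edit distance otherwise), each other record is globally aligned
#' to the star (match +1, mismatch -1, gap -2, linear), and the pairwise
#' alignments are merged by gap propagation.  The external method shells
#' out to a configured aligner executable reading/writing FASTA.
#'
#' @param records Record data.frame (at least 2 rows).
#' @param method `"builtin_centerstar"` or `"external"`.
#' @param aligner Path or name of the external aligner executable.
#' @param aligner_args Argument vector; the input FASTA path is appended
#'   and the aligned FASTA is read from standard output (MAFFT
#'   convention).
#' @return Character matrix over `{A,C,G,T,-}` with record IDs as row
#'   names, rows in input order.
#' @export
build_msa <- function(records,
                      method = c("builtin_centerstar", "external"),
                      aligner = "mafft",
                      aligner_args = c("--auto", "--quiet")) {
  method <- match.arg(method)
  if (nrow(records) < 2L) {
    stop("alignment needs at least 2 records", call. = FALSE)
  }
  if (method == "external") {
    return(build_msa_external(records, aligner, aligner_args))
  }
  build_msa_centerstar(records)
}

build_msa_external <- function(records, aligner, aligner_args) {
  if (Sys.which(aligner) == "" && !file.exists(aligner)) {
    stop(sprintf("external aligner not found: %s", aligner),
         call. = FALSE)
  }
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_fasta_tax(records, fin)
  status <- system2(aligner, c(aligner_args, fin), stdout = fout)
  if (status != 0L) {
    stop(sprintf("external aligner '%s' exited with status %d",
                 aligner, status), call. = FALSE)
  }
  aln <- Biostrings::readBStringSet(fout)
  ids <- sub("\\s.*$", "", names(aln))
  m <- aln_matrix_from_strings(as.character(aln), ids)
  # restore input order; external tools may reorder
  m[match(records$record_id, rownames(m)), , drop = FALSE]
}

# Center-star with a stable coordinate frame: every record is globally
# aligned to the star and projected onto the star's residue columns
# (equivalently, after gap propagation the columns in which the star
# carries a gap -- insertions relative to the star -- are trimmed).  The
# alignment therefore always has exactly as many columns as the star has
# residues, which keeps the downstream anchored frame stable; residues
# inserted relative to the star are dropped, a deliberate trade made by
# reference-anchored rRNA profiling generally.
build_msa_centerstar <- function(records) {
  seqs <- toupper(records$sequence)
  n <- length(seqs)
  d <- star_distances(seqs)
  center <- which.min(colSums(d))
  others <- setdiff(seq_len(n), center)

  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1,
                                                     baseOnly = FALSE)
  master <- strsplit(seqs[center], "", fixed = TRUE)[[1]]
  out <- matrix("-", nrow = n, ncol = length(master))
  out[center, ] <- master
  for (i in others) {
    pa <- Biostrings::pairwiseAlignment(seqs[i], seqs[center],
                                        type = "global",
                                        substitutionMatrix = submat,
                                        gapOpening = 0, gapExtension = 2)
    seq_aln <- strsplit(as.character(Biostrings::alignedPattern(pa)),
                        "", fixed = TRUE)[[1]]
    cen_aln <- strsplit(as.character(Biostrings::alignedSubject(pa)),
                        "", fixed = TRUE)[[1]]
    out[i, ] <- seq_aln[cen_aln != "-"]
  }
  out <- matrix(normalize_aln_chars(out), nrow = n)
  rownames(out) <- records$record_id
  out
}

star_distances <- function(seqs) {
  n <- length(seqs)
  if (length(unique(nchar(seqs))) == 1L) {
    chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    d <- matrix(0L, n, n)
    for (i in seq_len(n - 1L)) {
      rest <- (i + 1L):n
      di <- rowSums(chars[rest, , drop = FALSE] !=
                      matrix(chars[i, ], length(rest), ncol(chars),
                             byrow = TRUE))
      d[i, rest] <- di
      d[rest, i] <- di
    }
    d
  } else {
    utils::adist(seqs)
  }
}

#' Trim an alignment to the anchored 1,500-column frame
#'
#' Locates the conserved 5' marker in the per-column consensus (up to
#' `max_mismatch` substitutions, gap columns counting as mismatches) and
#' returns the `frame_len` columns starting at the marker's first base,
#' so frame position 1 is the start of conserved region 1.  If fewer
#' columns remain the frame is right-padded with all-gap columns and the
#' result carries attribute `padded = TRUE`.
#'
#' @param msa Alignment matrix from [build_msa()].
#' @param marker Conserved 5' marker sequence.
#' @param frame_len Frame width in columns.
#' @param max_mismatch Substitutions tolerated when locating the marker.
#' @return Alignment matrix of exactly `frame_len` columns, with
#'   attributes `frame_anchor` (source column of frame position 1) and
#'   `padded`.
#' @export
anchor_trim <- function(msa, marker = "AGAGTTTGATCATGGCTCAG",
                        frame_len = 1500L, max_mismatch = 2L) {
  cons <- apply(msa, 2L, majority_char)
  mk <- strsplit(toupper(marker), "", fixed = TRUE)[[1]]
  k <- length(mk)
  n <- length(cons)
  if (n < k) stop("alignment shorter than the anchor marker", call. = FALSE)
  nwin <- n - k + 1L
  mm <- vapply(seq_len(nwin), function(s) {
    sum(cons[s:(s + k - 1L)] != mk)
  }, integer(1))
  best <- which.min(mm)
  if (mm[best] > max_mismatch) {
    stop(sprintf("anchor marker not found in consensus (best window has %d mismatches)",
                 mm[best]), call. = FALSE)
  }
  a <- which(mm == mm[best])[1]
  end <- min(n, a + frame_len - 1L)
  out <- msa[, a:end, drop = FALSE]
  padded <- ncol(out) < frame_len
  if (padded) {
    pad <- matrix("-", nrow(out), frame_len - ncol(out))
    out <- cbind(out, pad)
  }
  rownames(out) <- rownames(msa)
  attr(out, "frame_anchor") <- a
  attr(out, "padded") <- padded
  out
}

# Most frequent character of a column; gaps win only if they are the
# strict majority of rows.  Ties among bases resolve alphabetically
# (deterministic; only used for anchor location).
majority_char <- function(col) {
  base <- col[col != "-"]
  if (length(base) * 2L < length(col)) return("-")
  tab <- table(base)
  names(tab)[which.max(tab)]
}
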