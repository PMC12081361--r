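# FASTA / taxonomy / primer-table input-output.
#
# Sequence records travel through the package as a plain data.frame with
# columns record_id, domain, phylum, class, order, family, genus (empty
# string where unknown) and sequence (uppercase IUPAC, U already converted
# to T).  Helper `tax_records()` builds one with the right shape.

.TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Construct a taxonomically annotated sequence record table
#'
#' @param record_id Character vector of sequence identifiers.
#' @param sequence Character vector of nucleotide sequences (IUPAC).
#' @param lineage Either `NULL` (all ranks unknown), a character vector of
#'   `;`-separated lineages (domain;phylum;class;order;family;genus,
#'   trailing ranks may be absent), or a data.frame with rank columns.
#' @return data.frame with columns `record_id`, the six rank columns and
#'   `sequence`.
#' @export
tax_records <- function(record_id, sequence, lineage = NULL) {
  stopifnot(length(record_id) == length(sequence))
  sequence <- toupper(sequence)
  sequence <- gsub("U", "T", sequence, fixed = TRUE)
  n <- length(record_id)
  ranks <- matrix("", nrow = n, ncol = length(.TAX_RANKS),
                  dimnames = list(NULL, .TAX_RANKS))
  if (is.data.frame(lineage)) {
    for (r in intersect(.TAX_RANKS, names(lineage))) {
      ranks[, r] <- as.character(lineage[[r]])
    }
  } else if (!is.null(lineage)) {
    parts <- strsplit(lineage, ";", fixed = TRUE)
    for (i in seq_len(n)) {
      p <- trimws(parts[[i]])
      k <- min(length(p), length(.TAX_RANKS))
      if (k > 0) ranks[i, seq_len(k)] <- p[seq_len(k)]
    }
  }
  out <- data.frame(record_id = as.character(record_id),
                    ranks, sequence = sequence,
                    stringsAsFactors = FALSE)
  ok <- nchar(out$sequence) > 0L
  if (!all(ok)) {
    stop(sprintf("record '%s' has an empty sequence",
                 out$record_id[which(!ok)[1]]), call. = FALSE)
  }
  out
}

#' Read a FASTA file with taxonomy
#'
#' Supports three taxonomy dialects: `silva_header` (first whitespace token
#' is the ID, remainder is a `;`-separated lineage, SILVA export style),
#' `ncbi_header` (first token is the ID, description kept but no lineage),
#' and `sidecar_tsv` (lineage joined from a two-column tab-separated file:
#' `record_id<TAB>domain;phylum;class;order;family;genus`).
#'
#' Sequences are uppercased and `U` is normalised to `T`.
#'
#' @param path FASTA file (multi-line records allowed).
#' @param dialect One of `"silva_header"`, `"ncbi_header"`, `"sidecar_tsv"`.
#' @param taxonomy Path to the sidecar TSV (required for `sidecar_tsv`).
#' @return A record data.frame as produced by [tax_records()].
#' @export
read_fasta_tax <- function(path,
                           dialect = c("silva_header", "ncbi_header",
                                       "sidecar_tsv"),
                           taxonomy = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    stop(sprintf("empty FASTA input: %s", path), call. = FALSE)
  }
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  lineage <- NULL
  if (dialect == "silva_header") {
    rest <- sub("^\\S+\\s*", "", headers)
    lineage <- ifelse(rest == headers | rest == "", "", rest)
  } else if (dialect == "sidecar_tsv") {
    if (is.null(taxonomy)) {
      stop("dialect 'sidecar_tsv' requires a `taxonomy` file", call. = FALSE)
    }
    map <- utils::read.delim(taxonomy, header = FALSE, sep = "\t",
                             colClasses = "character",
                             col.names = c("record_id", "lineage"))
    lineage <- map$lineage[match(ids, map$record_id)]
    lineage[is.na(lineage)] <- ""
  }
  tax_records(ids, as.character(seqs), lineage)
}

#' Write records to FASTA with SILVA-style lineage headers
#'
#' @param records A record data.frame.
#' @param path Output file.
#' @param width Residues per line.
#' @return `path`, invisibly.
#' @export
write_fasta_tax <- function(records, path, width = 70L) {
  lin <- apply(records[, .TAX_RANKS, drop = FALSE], 1L,
               function(x) {
                 x <- as.character(x)
                 last <- max(c(0L, which(x != "")))
                 paste(x[seq_len(last)], collapse = ";")
               })
  hdr <- ifelse(lin == "", records$record_id,
                paste(records$record_id, lin))
  seqs <- Biostrings::BStringSet(records$sequence)
  names(seqs) <- hdr
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Write the sidecar taxonomy TSV for a record table
#'
#' @inheritParams write_fasta_tax
#' @export
write_taxonomy_tsv <- function(records, path) {
  lin <- apply(records[, .TAX_RANKS, drop = FALSE], 1L,
               paste, collapse = ";")
  utils::write.table(data.frame(records$record_id, lin),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a degenerate primer-pair table
#'
#' Tab-separated with header columns `set_id`, `region_tag`, `forward`,
#' `reverse` and optional `forward_name`, `reverse_name`.  Both oligos are
#' written 5'->3' in IUPAC code; the reverse primer is given as ordered on
#' its own strand, not reverse-complemented.
#'
#' @param path Primer table file.
#' @return data.frame of validated primer pairs, one row per set.
#' @export
read_primer_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           comment.char = "#")
  required <- c("set_id", "region_tag", "forward", "reverse")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop(sprintf("primer table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) == 0L) return(tab[, required, drop = FALSE])
  dup <- tab$set_id[duplicated(tab$set_id)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate set_id in primer table: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  tab$forward <- toupper(tab$forward)
  tab$reverse <- toupper(tab$reverse)
  for (i in seq_len(nrow(tab))) {
    for (col in c("forward", "reverse")) {
      if (!is_iupac_string(tab[[col]][i])) {
        stop(sprintf("invalid IUPAC oligo in %s of set '%s'",
                     col, tab$set_id[i]), call. = FALSE)
      }
    }
  }
  tab
}

#' Remove primer pairs duplicating an earlier entry
#'
#' Two pairs are duplicates iff the forward sequences are identical AND
#' the reverse sequences are identical (case-insensitive, literal string
#' comparison -- degenerate pools spelt differently are NOT collapsed).
#' The first occurrence is kept and input order preserved.
#'
#' @param pairs Primer-pair data.frame from [read_primer_table()].
#' @return List with `unique` (deduplicated data.frame) and `removed`
#'   (number of rows dropped).
#' @export
dedupe_primer_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(list(unique = pairs, removed = 0L))
  key <- paste(toupper(pairs$forward), toupper(pairs$reverse), sep = "|")
  keep <- !duplicated(key)
  list(unique = pairs[keep, , drop = FALSE],
       removed = sum(!keep))
}
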