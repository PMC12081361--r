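# Degeneracy-exact in silico PCR.
#
# The matching rule: a primer matches a template window iff at every
# offset the template symbol's IUPAC expansion is a SUBSET of the primer
# symbol's expansion.  Perfect alignment is required within the designed
# degeneracy; no mismatches are tolerated outside degenerate positions.
# An ambiguous template base (e.g. N) therefore never matches a stricter
# primer base -- unknown residues are not counted as amplified.
#
# With the bitmask encoding (A=1, C=2, G=4, T=8) the subset test is
# bitwAnd(template, bitwNot(primer)) == 0, so a full scan is a handful of
# vectorised integer operations per primer position.

#' Does a degenerate primer match a template at a given position?
#'
#' @param primer IUPAC primer string, 5'->3'.
#' @param template IUPAC template string (sense strand).
#' @param pos 1-based start position of the candidate window.
#' @return `TRUE` iff every template symbol in the window expands to a
#'   subset of the corresponding primer symbol's expansion.
#' @export
matches_at <- function(primer, template, pos) {
  p <- iupac_bits(primer, "primer")
  t <- iupac_bits(template, "template")
  k <- length(p)
  if (pos < 1L || pos > length(t) - k + 1L) {
    stop(sprintf("position %d out of range for a %d-nt window on a %d-nt template",
                 pos, k, length(t)), call. = FALSE)
  }
  all(bitwAnd(t[pos:(pos + k - 1L)], bitwNot(p)) == 0L)
}

#' Find all degeneracy-exact primer sites on a template
#'
#' @inheritParams matches_at
#' @return Ascending 1-based start positions of every matching window;
#'   overlapping sites are all reported.  A primer longer than the
#'   template yields an empty result.
#' @export
find_sites <- function(primer, template) {
  p <- iupac_bits(primer, "primer")
  t <- iupac_bits(template, "template")
  find_sites_bits(p, t)
}

# Core scan on pre-encoded bitmask vectors (shared with coverage loops).
find_sites_bits <- function(p, t) {
  k <- length(p)
  n <- length(t) - k + 1L
  if (n < 1L) return(integer(0))
  ok <- rep(TRUE, n)
  for (i in seq_len(k)) {
    ok <- ok & (bitwAnd(t[i:(i + n - 1L)], bitwNot(p[i])) == 0L)
  }
  which(ok)
}

#' Predict amplicons for a primer pair on one template
#'
#' Templates are assumed deposited 5'->3' on the gene's sense strand (as
#' in SSU rRNA databases); the forward primer is matched directly and the
#' reverse primer as its reverse complement strictly downstream of the
#' forward site.  Coordinates are 1-based inclusive and amplicon lengths
#' include both primers.
#'
#' @param pair One-row primer-pair data.frame (columns `forward`,
#'   `reverse`), or a list with those elements.
#' @param record One-row record data.frame (columns `record_id`,
#'   `sequence`), or a list with those elements.
#' @param max_len Maximum amplicon length to report (guards against
#'   pathological pairings; predicted 16S amplicons are under 1.5 kb).
#' @return data.frame with columns `record_id`, `fwd_start`, `rev_end`,
#'   `amplicon_len`, sorted by `fwd_start` then `amplicon_len`.
#' @export
predict_amplicons <- function(pair, record, max_len = 4000L) {
  fwd <- pair$forward
  rev <- pair$reverse
  if (max_len < nchar(fwd) + nchar(rev)) {
    stop("`max_len` is shorter than the two primers combined",
         call. = FALSE)
  }
  t <- iupac_bits(record$sequence, "template")
  hits <- amplicon_spans(iupac_bits(fwd, "forward primer"),
                         iupac_bits(reverse_complement(rev),
                                    "reverse primer"),
                         t, max_len)
  data.frame(record_id = rep(record$record_id, nrow(hits)), hits,
             stringsAsFactors = FALSE)
}

# Span arithmetic on encoded vectors; p_rc is the reverse-complemented
# reverse primer.  Returns fwd_start/rev_end/amplicon_len columns.
amplicon_spans <- function(p_fwd, p_rc, t, max_len) {
  f <- find_sites_bits(p_fwd, t)
  r <- find_sites_bits(p_rc, t)
  empty <- data.frame(fwd_start = integer(0), rev_end = integer(0),
                      amplicon_len = integer(0))
  if (length(f) == 0L || length(r) == 0L) return(empty)
  kf <- length(p_fwd)
  kr <- length(p_rc)
  out <- expand.grid(fwd_start = f, rev_start = r)
  out <- out[out$rev_start > out$fwd_start + kf - 1L, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out$rev_end <- out$rev_start + kr - 1L
  out$amplicon_len <- out$rev_end - out$fwd_start + 1L
  out <- out[out$amplicon_len <= max_len, , drop = FALSE]
  out <- out[order(out$fwd_start, out$amplicon_len), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("fwd_start", "rev_end", "amplicon_len")]
}

#' Per-taxon amplification coverage of primer pairs
#'
#' Coverage is the percentage of a taxon's eligible sequences predicted to
#' be amplified (at least one amplicon) by a primer pair.  Eligible means
#' the requested rank is populated; records without a label at that rank
#' are excluded from denominators.  A record with several amplicons still
#' counts once.
#'
#' @param pairs Primer-pair data.frame.
#' @param records Record data.frame.
#' @param rank One of `"phylum"`, `"family"`, `"genus"`.
#' @param max_len Passed to the amplicon predictor.
#' @param min_length Optional minimum template length; `NULL` (default)
#'   disables the filter.  Intended for raw database exports.
#' @return Object of class `coverage_table`: list with `rank`, `cells`
#'   (long data.frame: taxon, set_id, covered, denominator, percent) and
#'   `denominators` (named integer vector).
#' @export
coverage_table <- function(pairs, records, rank = c("phylum", "family",
                                                    "genus"),
                           max_len = 4000L, min_length = NULL) {
  rank <- match.arg(rank)
  lab <- records[[rank]]
  keep <- !is.na(lab) & lab != ""
  if (!is.null(min_length)) keep <- keep & nchar(records$sequence) >= min_length
  if (!any(keep)) {
    stop(sprintf("no record has a populated '%s' label", rank),
         call. = FALSE)
  }
  records <- records[keep, , drop = FALSE]
  lab <- lab[keep]
  tmpl <- lapply(records$sequence, iupac_bits, what = "template")
  taxa <- unique(lab)
  cells <- vector("list", nrow(pairs))
  for (j in seq_len(nrow(pairs))) {
    p_fwd <- iupac_bits(pairs$forward[j], "forward primer")
    p_rc <- iupac_bits(reverse_complement(pairs$reverse[j]),
                       "reverse primer")
    amp <- vapply(tmpl, function(t) {
      nrow(amplicon_spans(p_fwd, p_rc, t, max_len)) > 0L
    }, logical(1))
    cov <- tapply(amp, factor(lab, levels = taxa), sum)
    den <- tapply(rep(1L, length(lab)), factor(lab, levels = taxa), sum)
    cells[[j]] <- data.frame(taxon = taxa,
                             set_id = pairs$set_id[j],
                             covered = as.integer(cov),
                             denominator = as.integer(den),
                             percent = 100 * as.integer(cov) /
                               as.integer(den),
                             stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  den <- table(factor(lab, levels = taxa))
  structure(list(rank = rank, cells = cells,
                 denominators = stats::setNames(as.integer(den), taxa)),
            class = "coverage_table")
}

#' @export
print.coverage_table <- function(x, ...) {
  cat(sprintf("coverage_table: rank=%s, %d taxa x %d primer sets\n",
              x$rank, length(x$denominators),
              length(unique(x$cells$set_id))))
  invisible(x)
}

#' Wide taxa-by-primer coverage matrix
#'
#' @param tbl A `coverage_table`.
#' @return Numeric matrix, taxa in rows, primer sets in columns, percent
#'   coverage in cells.
#' @export
coverage_matrix <- function(tbl) {
  taxa <- names(tbl$denominators)
  sets <- unique(tbl$cells$set_id)
  m <- matrix(NA_real_, length(taxa), length(sets),
              dimnames = list(taxa, sets))
  m[cbind(match(tbl$cells$taxon, taxa),
          match(tbl$cells$set_id, sets))] <- tbl$cells$percent
  m
}

coverage_lookup <- function(tbl, taxa, set_id) {
  idx <- match(paste(taxa, set_id), paste(tbl$cells$taxon,
                                          tbl$cells$set_id))
  tbl$cells$percent[idx]
}

#' Two-stage primer candidate selection
#'
#' Stage one requires coverage at or above `phylum_thr` percent in every
#' named phylum; stage two requires coverage at or above `genus_thr`
#' percent in at least `min_genera` of the named genera.  Both thresholds
#' are inclusive.
#'
#' @param phylum_tbl,genus_tbl `coverage_table`s at phylum and genus rank.
#' @param phyla,genera Taxon labels the rules are evaluated on (four
#'   dominant phyla; twenty representative genera).
#' @param phylum_thr,genus_thr,min_genera Selection thresholds.
#' @return data.frame with one row per primer set: `set_id`,
#'   `phylum_pass`, `qualifying_genera`, `candidate`.
#' @export
select_candidates <- function(phylum_tbl, genus_tbl, phyla, genera,
                              phylum_thr = 70, genus_thr = 90,
                              min_genera = 4L) {
  miss_p <- setdiff(phyla, names(phylum_tbl$denominators))
  miss_g <- setdiff(genera, names(genus_tbl$denominators))
  if (length(miss_p) + length(miss_g) > 0L) {
    stop(sprintf("taxa missing from coverage tables: %s",
                 paste(c(miss_p, miss_g), collapse = ", ")),
         call. = FALSE)
  }
  sets <- unique(phylum_tbl$cells$set_id)
  res <- lapply(sets, function(s) {
    pcov <- coverage_lookup(phylum_tbl, phyla, s)
    gcov <- coverage_lookup(genus_tbl, genera, s)
    phylum_pass <- all(pcov >= phylum_thr)
    qualifying <- sum(gcov >= genus_thr, na.rm = TRUE)
    data.frame(set_id = s, phylum_pass = phylum_pass,
               qualifying_genera = qualifying,
               candidate = phylum_pass && qualifying >= min_genera,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
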