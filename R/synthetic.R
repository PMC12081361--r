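# Synthetic 16S-like sequence generator with known ground truth.
#
# Emulates the canonical architecture of the gene -- nine hypervariable
# regions (V1-V9) interspersed with ten conserved regions (C1-C10) in a
# 1,542-nt frame -- with genus-level clades substituting conserved and
# variable columns at distinct rates, and primer binding sites carrying
# planted mismatch fractions so true coverage is known by construction.
# Substitution-only by default, so frame coordinates stay exact; an
# optional indel layer is deliberately absent from the defaults.

QC_MARKER <- "AGAGTTTGATCATGGCTCAG"

# Conventional E. coli frame coordinates for the nine variable regions.
.DEFAULT_V_REGIONS <- data.frame(
  label = paste0("V", 1:9),
  start = c(69L, 137L, 433L, 576L, 822L, 986L, 1117L, 1243L, 1435L),
  end   = c(99L, 242L, 497L, 682L, 879L, 1043L, 1173L, 1294L, 1465L),
  stringsAsFactors = FALSE
)

#' Gene layout: conserved/variable architecture of the synthetic gene
#'
#' Builds and validates a layout in which conserved (C1-C10) and variable
#' (V1-V9) blocks alternate and tile `[1, total_len]`.  The per-column
#' substitution probabilities `p_cons` and `p_var` are the rates at which
#' [evolve_genus()] mutates conserved and variable columns.
#'
#' @param total_len Gene length in nt.
#' @param v_regions data.frame of variable blocks (`label`, `start`,
#'   `end`, 1-based inclusive); conserved blocks fill the gaps.
#' @param p_cons,p_var Per-column substitution probabilities; must
#'   satisfy `0 <= p_cons < p_var <= 0.75`.
#' @return Object of class `gene_layout`: list with `total_len`,
#'   `regions` (tiling data.frame with `label`, `start`, `end`, `type`),
#'   `p_cons`, `p_var`.
#' @export
gene_layout <- function(total_len = 1542L, v_regions = .DEFAULT_V_REGIONS,
                        p_cons = 0.01, p_var = 0.30) {
  if (!(p_cons >= 0 && p_cons < p_var && p_var <= 0.75)) {
    stop("substitution rates must satisfy 0 <= p_cons < p_var <= 0.75",
         call. = FALSE)
  }
  v <- v_regions[order(v_regions$start), , drop = FALSE]
  if (nrow(v) > 0L &&
      (v$start[1] <= 1L || v$end[nrow(v)] >= total_len ||
       any(v$start > v$end) ||
       any(v$start[-1] <= v$end[-nrow(v)] + 1L))) {
    stop("variable blocks must be ordered, disjoint, separated by conserved columns and strictly inside [1, total_len]",
         call. = FALSE)
  }
  regions <- list()
  pos <- 1L
  for (i in seq_len(nrow(v))) {
    regions[[length(regions) + 1L]] <-
      data.frame(label = paste0("C", i), start = pos,
                 end = v$start[i] - 1L, type = "conserved")
    regions[[length(regions) + 1L]] <-
      data.frame(label = v$label[i], start = v$start[i], end = v$end[i],
                 type = "variable")
    pos <- v$end[i] + 1L
  }
  regions[[length(regions) + 1L]] <-
    data.frame(label = paste0("C", nrow(v) + 1L), start = pos,
               end = total_len, type = "conserved")
  regions <- do.call(rbind, regions)
  rownames(regions) <- NULL
  structure(list(total_len = as.integer(total_len), regions = regions,
                 p_cons = p_cons, p_var = p_var),
            class = "gene_layout")
}

#' Per-column substitution probabilities implied by a layout
#' @param layout A `gene_layout`.
#' @return Numeric vector of length `total_len`.
#' @export
layout_rates <- function(layout) {
  p <- rep(layout$p_cons, layout$total_len)
  vr <- layout$regions[layout$regions$type == "variable", , drop = FALSE]
  for (i in seq_len(nrow(vr))) p[vr$start[i]:vr$end[i]] <- layout$p_var
  p
}

#' Variable-region spans of a layout
#' @param layout A `gene_layout`.
#' @return data.frame `label`, `start`, `end` of the variable blocks.
#' @export
layout_variable_spans <- function(layout) {
  vr <- layout$regions[layout$regions$type == "variable",
                       c("label", "start", "end")]
  rownames(vr) <- NULL
  vr
}

#' Sample an ancestral backbone sequence
#'
#' Uniform random residues per column, with the conserved 5' QC marker
#' written verbatim at columns 1-20 (inside C1) so generated data passes
#' [qc_marker_filter()].
#'
#' @param layout A `gene_layout` with `total_len >= 20`.
#' @param seed Integer seed.
#' @param record_id ID of the returned record.
#' @return One-row record data.frame.
#' @export
sample_backbone <- function(layout, seed = 1L, record_id = "backbone") {
  if (layout$total_len < nchar(QC_MARKER)) {
    stop("layout too short to carry the 5' QC marker", call. = FALSE)
  }
  res <- withr::with_seed(seed,
    sample(c("A", "C", "G", "T"), layout$total_len, replace = TRUE))
  res[seq_len(nchar(QC_MARKER))] <-
    strsplit(QC_MARKER, "", fixed = TRUE)[[1]]
  tax_records(record_id, paste(res, collapse = ""))
}

#' Evolve a genus clade from a backbone
#'
#' Each of `n` sequences independently substitutes each column with
#' probability `p_cons` (conserved columns) or `p_var` (variable
#' columns), drawing uniformly among the three alternative bases.  The
#' QC marker columns (1-20) are held fixed so every sequence passes the
#' 5'-marker QC.
#'
#' @param backbone One-row record data.frame (the clade ancestor).
#' @param n Number of sequences (at least 2).
#' @param layout The `gene_layout` supplying rates.
#' @param seed Integer seed.
#' @param genus Genus label planted in the lineage.
#' @param lineage Named character vector overriding other ranks
#'   (defaults to a synthetic Bacteria lineage).
#' @param protect_marker Hold columns 1-20 invariant (default `TRUE`).
#' @return Record data.frame with `n` rows, IDs `<genus>_1 ...`.
#' @export
evolve_genus <- function(backbone, n, layout, seed = 1L,
                         genus = "Genussyn",
                         lineage = c(domain = "Bacteria",
                                     phylum = "Synthphylum",
                                     class = "Synthclass",
                                     order = "Synthorder",
                                     family = "Synthfamily"),
                         protect_marker = TRUE) {
  stopifnot(n >= 2L)
  base <- strsplit(backbone$sequence[1], "", fixed = TRUE)[[1]]
  L <- length(base)
  p <- layout_rates(layout)[seq_len(L)]
  if (protect_marker) p[seq_len(min(L, nchar(QC_MARKER)))] <- 0
  seqs <- withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      mut <- stats::runif(L) < p
      out <- base
      if (any(mut)) {
        out[mut] <- vapply(base[mut], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, character(1), USE.NAMES = FALSE)
      }
      paste(out, collapse = "")
    }, character(1))
  })
  lin <- data.frame(t(lineage), genus = genus, stringsAsFactors = FALSE)
  tax_records(paste0(genus, "_", seq_len(n)), seqs,
              lin[rep(1L, n), , drop = FALSE])
}

#' Plant an exact fraction of primer-site-destroying mismatches
#'
#' Exactly `round(fraction * n)` records (chosen uniformly under `seed`)
#' receive one substitution at the site's 3'-terminal column, to a base
#' outside the evaluating primer's expansion at that position -- so those
#' records can no longer be amplified via this site and the true
#' coverage is `100 * (1 - round(q n)/n)` percent by construction.
#' Placing the mismatch at the 3' end also exercises the 3'-flag logic
#' of the binding analysis.
#'
#' @param records Record data.frame (one genus).
#' @param site `c(start, end)` 1-based template span of the primer site.
#' @param fraction Fraction `q` of records to mutate, in `[0, 1]`.
#' @param primer The primer occupying the site, 5'->3' as it reads on the
#'   template (pass the reverse complement for a reverse-primer site).
#' @param seed Integer seed.
#' @return List with `records` (modified) and `truth` (list: `genus`,
#'   `site`, `n`, `n_mutated`, `expected_coverage` percent, `seed`).
#' @export
plant_site_mismatches <- function(records, site, fraction, primer,
                                  seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1, length(site) == 2L)
  n <- nrow(records)
  if (site[1] < 1L || site[2] > min(nchar(records$sequence)) ||
      site[2] - site[1] + 1L != nchar(primer)) {
    stop("site does not fit the templates or the primer length",
         call. = FALSE)
  }
  m <- round(fraction * n)
  pos <- site[2]
  allowed <- expand_iupac(substr(primer, nchar(primer), nchar(primer)))
  forbidden <- setdiff(c("A", "C", "G", "T"), allowed)
  if (length(forbidden) == 0L) {
    stop("primer 3'-terminal position is fully degenerate; no destroying base exists",
         call. = FALSE)
  }
  if (m > 0L) {
    pick <- withr::with_seed(seed, sample.int(n, m))
    for (i in pick) {
      cur <- substr(records$sequence[i], pos, pos)
      new <- setdiff(forbidden, cur)[1]
      substr(records$sequence[i], pos, pos) <- new
    }
  }
  truth <- list(genus = records$genus[1], site = as.integer(site),
                n = n, n_mutated = as.integer(m),
                expected_coverage = 100 * (1 - m / n), seed = seed)
  list(records = records, truth = truth)
}

#' Generate a mock multi-copy community
#'
#' Emulates a defined standard of known strains in which each genome
#' carries several near-identical 16S copies: per strain, one reference
#' is evolved from the backbone at the layout's rates, then
#' `copies_per_strain[i]` copies are drawn from it at a small
#' within-genome divergence.  Defaults give 19 strains and 110 total
#' sequences.
#'
#' @param strains Number of strains.
#' @param copies_per_strain Integer vector of copy numbers (recycled to
#'   `strains`); the default sums to 110.
#' @param layout A `gene_layout`.
#' @param seed Integer seed.
#' @param copy_rate Per-column substitution probability between copies of
#'   one genome.
#' @return List with `records` (one row per gene copy, genus label
#'   `StrainNN`) and `truth` (list: `strains`, `copies_per_strain`,
#'   `total`, `seed`).
#' @export
make_mock_community <- function(strains = 19L,
                                copies_per_strain = rep(c(6L, 5L),
                                                        c(15L, 4L)),
                                layout = gene_layout(), seed = 1L,
                                copy_rate = 0.002) {
  stopifnot(strains >= 1L, all(copies_per_strain >= 1L))
  copies <- rep_len(copies_per_strain, strains)
  backbone <- sample_backbone(layout, seed = seed)
  out <- vector("list", strains)
  for (s in seq_len(strains)) {
    genus <- sprintf("Strain%02d", s)
    ref <- evolve_genus(backbone, 2L, layout, seed = seed + s,
                        genus = genus)[1L, , drop = FALSE]
    if (copies[s] == 1L) {
      ref$record_id <- paste0(genus, "_copy1")
      out[[s]] <- ref
    } else {
      cps <- evolve_copies(ref, copies[s], copy_rate,
                           seed = seed + 1000L + s)
      out[[s]] <- cps
    }
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  list(records = records,
       truth = list(strains = as.integer(strains),
                    copies_per_strain = as.integer(copies),
                    total = nrow(records), seed = seed))
}

# Near-identical within-genome copies of one reference record.
evolve_copies <- function(ref, n_copies, copy_rate, seed) {
  base <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  L <- length(base)
  p <- rep(copy_rate, L)
  p[seq_len(min(L, nchar(QC_MARKER)))] <- 0
  seqs <- withr::with_seed(seed, {
    vapply(seq_len(n_copies), function(i) {
      if (i == 1L) return(paste(base, collapse = ""))  # copy 1 = reference
      mut <- stats::runif(L) < p
      out <- base
      if (any(mut)) {
        out[mut] <- vapply(base[mut], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, character(1), USE.NAMES = FALSE)
      }
      paste(out, collapse = "")
    }, character(1))
  })
  lin <- ref[rep(1L, n_copies), .TAX_RANKS, drop = FALSE]
  tax_records(paste0(ref$genus, "_copy", seq_len(n_copies)), seqs, lin)
}
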