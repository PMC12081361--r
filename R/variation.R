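# Conserved/variable region profiling of aligned 16S genes.
#
# Pipeline order per genus: QC by the conserved 5' marker -> random
# subsample -> align -> anchor-trim to the 1,500-column frame -> per-column
# Shannon entropy -> threshold/merge segmentation into variable and
# conserved spans.

#' Quality-filter records by the conserved 5' marker
#'
#' A record is retained iff some window starting within the first
#' `max_offset` positions matches the full marker with at most
#' `max_mismatch` substitutions (no indels within the marker window).
#' This operationalises "aligning from the first position of conserved
#' region 1" while tolerating ragged 5' ends and light sequencing noise.
#'
#' @param records Record data.frame.
#' @param marker Conserved 5' marker (default is the canonical 20-mer at
#'   the start of the 16S gene).
#' @param max_mismatch Substitutions tolerated in the marker window.
#' @param max_offset Latest allowed 1-based start of the marker window.
#' @return The retained subset of `records`.
#' @export
qc_marker_filter <- function(records, marker = "AGAGTTTGATCATGGCTCAG",
                             max_mismatch = 2L, max_offset = 5L) {
  stopifnot(nchar(marker) > 0L)
  if (nrow(records) == 0L) stop("no input records", call. = FALSE)
  mk <- strsplit(toupper(marker), "", fixed = TRUE)[[1]]
  k <- length(mk)
  keep <- vapply(records$sequence, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(chars)
    for (start in seq_len(max_offset)) {
      if (start + k - 1L > n) break
      if (sum(chars[start:(start + k - 1L)] != mk) <= max_mismatch) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
  records[keep, , drop = FALSE]
}

#' Random subsample of records, without replacement
#'
#' If `n` or fewer records are supplied all are returned (small genera
#' pass through untouched); otherwise a uniform sample without
#' replacement is drawn, reproducibly for a fixed seed.  The caller's RNG
#' state is left untouched.
#'
#' @param records Record data.frame.
#' @param n Target sample size.
#' @param seed Integer seed for the draw.
#' @return Record data.frame with `min(n, nrow(records))` rows, in
#'   original relative order.
#' @export
subsample <- function(records, n = 100L, seed = 42L) {
  stopifnot(n >= 1L)
  if (nrow(records) <= n) return(records)
  idx <- withr::with_seed(seed, sample.int(nrow(records), n))
  records[sort(idx), , drop = FALSE]
}

#' Shannon entropy of one alignment column
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} over the four bases, with
#' frequencies renormalised over non-gap residues and \eqn{0 \log 0 = 0}.
#' Ranges from 0 (invariant column) to 2 bits (uniform column).
#'
#' @param counts Named or positional counts over A, C, G, T (gaps already
#'   excluded); total must be at least 1.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(counts) {
  counts <- as.numeric(counts)
  total <- sum(counts)
  if (total < 1) stop("column has no residues", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log2(p)) + 0   # + 0 normalises IEEE negative zero
}

#' Per-column entropy profile of an alignment
#'
#' Gaps are excluded from each column and frequencies renormalised over
#' the non-gap residues; columns whose non-gap fraction falls below
#' `min_nongap_frac` are masked (value `NA`) and excluded from region
#' calls and means, which prevents terminal-gap artifacts from inflating
#' apparent variability.
#'
#' @param msa Alignment matrix over `{A,C,G,T,-}`.
#' @param min_nongap_frac Mask threshold on the non-gap fraction.
#' @return Object of class `entropy_profile`: list with `values` (bits,
#'   `NA` where masked), `n_eff` (non-gap count per column), `masked`
#'   (logical) and `frame_anchor` (propagated from [anchor_trim()], 1 if
#'   absent).
#' @export
entropy_profile <- function(msa, min_nongap_frac = 0.5) {
  stopifnot(nrow(msa) >= 1L)
  lv <- c("A", "C", "G", "T")
  counts <- apply(msa, 2L, function(col) tabulate(match(col, lv), 4L))
  n_eff <- colSums(counts)
  masked <- n_eff < min_nongap_frac * nrow(msa) | n_eff == 0L
  values <- rep(NA_real_, ncol(msa))
  for (j in which(!masked)) values[j] <- shannon_entropy(counts[, j])
  structure(list(values = values, n_eff = as.integer(n_eff),
                 masked = masked,
                 frame_anchor = attr(msa, "frame_anchor") %||% 1L),
            class = "entropy_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("entropy_profile: %d columns (%d masked), mean %.3f bits\n",
              length(x$values), sum(x$masked),
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Segment an entropy profile into variable and conserved regions
#'
#' Columns whose entropy exceeds `threshold` bits seed variable regions;
#' runs of seeds separated by at most `merge_gap` sub-threshold (or
#' masked) columns are merged; merged runs shorter than `min_len` columns
#' are dropped; the rest of the frame is labelled conserved.
#'
#' @param profile An `entropy_profile`.
#' @param threshold Entropy threshold in bits; columns strictly above it
#'   are variable seeds.
#' @param merge_gap Maximum sub-threshold run length bridged when
#'   merging.
#' @param min_len Minimum retained variable-span length in columns.
#' @return Object of class `region_annotation`: data.frame of disjoint
#'   sorted spans (`start`, `end`, `label`, `mean_entropy`) tiling the
#'   frame, with the call parameters as attributes.
#' @export
call_regions <- function(profile, threshold = 0.5, merge_gap = 5L,
                         min_len = 10L) {
  v <- profile$values
  n <- length(v)
  stopifnot(n >= 1L)
  seeds <- which(!is.na(v) & v > threshold)
  spans <- list()
  if (length(seeds) > 0L) {
    run_start <- seeds[1]
    run_end <- seeds[1]
    for (s in seeds[-1]) {
      if (s - run_end - 1L <= merge_gap) {
        run_end <- s
      } else {
        spans[[length(spans) + 1L]] <- c(run_start, run_end)
        run_start <- s
        run_end <- s
      }
    }
    spans[[length(spans) + 1L]] <- c(run_start, run_end)
  }
  spans <- Filter(function(sp) sp[2] - sp[1] + 1L >= min_len, spans)
  var_df <- if (length(spans) > 0L) {
    data.frame(start = vapply(spans, `[`, 0, 1),
               end = vapply(spans, `[`, 0, 2),
               label = "variable", stringsAsFactors = FALSE)
  } else {
    data.frame(start = integer(0), end = integer(0),
               label = character(0), stringsAsFactors = FALSE)
  }
  # conserved spans fill the complement of the variable spans
  out <- list()
  pos <- 1L
  for (i in seq_len(nrow(var_df))) {
    if (var_df$start[i] > pos) {
      out[[length(out) + 1L]] <- data.frame(start = pos,
                                            end = var_df$start[i] - 1L,
                                            label = "conserved")
    }
    out[[length(out) + 1L]] <- var_df[i, , drop = FALSE]
    pos <- var_df$end[i] + 1L
  }
  if (pos <= n) {
    out[[length(out) + 1L]] <- data.frame(start = pos, end = n,
                                          label = "conserved")
  }
  ann <- do.call(rbind, out)
  rownames(ann) <- NULL
  ann$mean_entropy <- vapply(seq_len(nrow(ann)), function(i) {
    vv <- v[ann$start[i]:ann$end[i]]
    if (all(is.na(vv))) NA_real_ else mean(vv, na.rm = TRUE)
  }, numeric(1))
  structure(ann, class = c("region_annotation", "data.frame"),
            threshold = threshold, merge_gap = merge_gap,
            min_len = min_len)
}

#' Variable spans of a region annotation
#' @param regions A `region_annotation`.
#' @return The rows labelled `variable`.
#' @export
variable_spans <- function(regions) {
  regions[regions$label == "variable", , drop = FALSE]
}

#' Mean entropy profile and per-genus entropy index
#'
#' @param profiles Named list of `entropy_profile`s sharing one frame
#'   width.
#' @return List with `mean_profile` (column-wise mean over unmasked
#'   values, `NA` where every genus is masked) and `index` (named vector:
#'   each genus's mean unmasked entropy).  Genera masked everywhere are
#'   excluded with a warning.
#' @export
summarize_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  widths <- vapply(profiles, function(p) length(p$values), integer(1))
  if (length(unique(widths)) != 1L) {
    bad <- names(profiles)[widths != widths[1]][1]
    stop(sprintf("profile frame mismatch for '%s' (%d columns, expected %d)",
                 bad, widths[names(profiles) == bad][1], widths[1]),
         call. = FALSE)
  }
  idx <- vapply(profiles, function(p) {
    if (all(p$masked)) NA_real_ else mean(p$values[!p$masked])
  }, numeric(1))
  dead <- names(idx)[is.na(idx)]
  if (length(dead) > 0L) {
    warning(sprintf("genus with all columns masked excluded: %s",
                    paste(dead, collapse = ", ")))
    profiles <- profiles[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  vals <- do.call(rbind, lapply(profiles, `[[`, "values"))
  mean_profile <- colMeans(vals, na.rm = TRUE)
  mean_profile[is.nan(mean_profile)] <- NA_real_
  list(mean_profile = mean_profile, index = idx)
}

#' Compare called variable regions to a canonical V1-V9 layout
#'
#' @param regions A `region_annotation` in frame coordinates.
#' @param canonical data.frame with columns `label`, `start`, `end`
#'   (1-based inclusive frame coordinates of the canonical variable
#'   regions).
#' @param frame_len Frame width used to validate the canonical
#'   coordinates.
#' @param mode `"any"` (default): a canonical region is detected when any
#'   called variable span overlaps it; `"reciprocal"`: require at least
#'   `min_reciprocal` overlap of both the canonical region and the
#'   calling span.
#' @param min_reciprocal Reciprocal-overlap fraction for
#'   `mode = "reciprocal"`.
#' @return data.frame per canonical region: `label`, `detected`,
#'   `overlap_fraction` (fraction of the canonical region covered by
#'   variable spans).
#' @export
compare_to_canonical <- function(regions, canonical, frame_len = 1500L,
                                 mode = c("any", "reciprocal"),
                                 min_reciprocal = 0.5) {
  mode <- match.arg(mode)
  if (any(canonical$start < 1L | canonical$end > frame_len |
            canonical$start > canonical$end)) {
    stop("canonical region coordinates fall outside the frame",
         call. = FALSE)
  }
  vs <- variable_spans(regions)
  out <- lapply(seq_len(nrow(canonical)), function(i) {
    cs <- canonical$start[i]; ce <- canonical$end[i]
    clen <- ce - cs + 1L
    ov <- pmax(0L, pmin(vs$end, ce) - pmax(vs$start, cs) + 1L)
    frac <- sum(ov) / clen
    detected <- if (mode == "any") {
      any(ov > 0L)
    } else {
      any(ov / clen >= min_reciprocal &
            ov / (vs$end - vs$start + 1L) >= min_reciprocal)
    }
    data.frame(label = canonical$label[i], detected = detected,
               overlap_fraction = frac, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
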