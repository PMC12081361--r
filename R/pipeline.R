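# Pipeline orchestration: configuration, the three analyses (coverage,
# variation, binding), the generator, and the report writers.
#
# Every machine-readable output carries a provenance block (tool version,
# configuration hash, seed) and is deterministic for a fixed
# configuration and seed; timestamps live only in log messages on
# stderr.

#' Build a run configuration
#'
#' Returns the default configuration, with any supplied named values
#' overriding defaults.  Paths are `NULL` until set.  The default
#' thresholds are the published selection rules: at least 70 percent
#' coverage in all four dominant phyla, at least 90 percent coverage in
#' at least four of twenty representative genera, and a 0.5-bit entropy
#' threshold for variable-region calls.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    sequences = NULL, taxonomy = NULL, dialect = "silva_header",
    primers = NULL, out_dir = "primerscreen_out", seed = 42L,
    phyla = NULL, genera = NULL,
    phylum_threshold = 70, genus_threshold = 90, min_genera = 4L,
    entropy_threshold = 0.5, merge_gap = 5L, min_region_len = 10L,
    subsample_n = 100L, max_len = 4000L, min_length = NULL,
    marker = QC_MARKER, frame_len = 1500L,
    aligner = "builtin_centerstar", aligner_path = "mafft",
    generate = list(n_genera = 20L, n_per_genus = 100L,
                    total_len = 1542L, p_cons = 0.01, p_var = 0.30,
                    v_regions = NULL, plant = NULL)
  )
  over <- list(...)
  bad <- setdiff(names(over), c(names(cfg)))
  if (length(bad) > 0L) {
    stop(sprintf("unknown configuration field(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(over)) {
    if (nm == "generate") {
      cfg$generate[names(over$generate)] <- over$generate
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are configuration fields.
#' @param ... Named overrides applied after the file (flags win).
#' @return A `run_config`.
#' @export
load_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(run_config, vals)
}

validate_config <- function(cfg) {
  stopifnot(cfg$phylum_threshold >= 0, cfg$phylum_threshold <= 100,
            cfg$genus_threshold >= 0, cfg$genus_threshold <= 100,
            cfg$min_genera >= 0, cfg$entropy_threshold >= 0,
            cfg$entropy_threshold <= 2, cfg$merge_gap >= 0,
            cfg$min_region_len >= 1, cfg$subsample_n >= 1,
            cfg$frame_len >= 1)
  invisible(cfg)
}

config_hash <- function(cfg) {
  # hash the scientific parameters only, not filesystem paths, so runs of
  # one configuration into different directories stay byte-identical
  sci <- cfg[setdiff(names(cfg), c("sequences", "taxonomy", "primers",
                                   "out_dir", "aligner_path"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(sci[order(names(sci))], tmp, auto_unbox = TRUE,
                       null = "null", digits = NA)
  unname(tools::md5sum(tmp))
}

provenance <- function(cfg) {
  list(tool = "primerscreen",
       version = as.character(utils::packageVersion("primerscreen")),
       config_hash = config_hash(cfg), seed = cfg$seed)
}

prov_header <- function(prov) {
  sprintf("# tool=%s %s\n# config_hash=%s\n# seed=%d",
          prov$tool, prov$version, prov$config_hash, as.integer(prov$seed))
}

write_tsv_prov <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov_header(prov), con)
  utils::write.table(format(df, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

log_msg <- function(...) message(sprintf("[primerscreen] %s",
                                         sprintf(...)))

#' Write region annotations as BED
#'
#' Converts the internal 1-based inclusive frame coordinates to BED's
#' 0-based half-open convention; `name` is the span label and `score` the
#' span's mean entropy times 1,000, truncated and capped at 1,000.
#'
#' @param regions_by_genus Named list of `region_annotation`s; the genus
#'   becomes the BED chrom field.
#' @param path Output file.
#' @param prov Provenance list (from an internal builder); `NULL` omits
#'   the header.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions_by_genus, path, prov = NULL) {
  rows <- lapply(names(regions_by_genus), function(g) {
    r <- regions_by_genus[[g]]
    score <- ifelse(is.na(r$mean_entropy), 0L,
                    pmin(1000L, as.integer(trunc(r$mean_entropy * 1000))))
    data.frame(chrom = g, start = r$start - 1L, end = r$end,
               name = r$label, score = score, stringsAsFactors = FALSE)
  })
  bed <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(prov)) writeLines(prov_header(prov), con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate a synthetic 16S database with ground truth
#'
#' Builds `n_genera` genus clades (assigned round-robin to four synthetic
#' phyla) from a common backbone, optionally plants primer-site mismatch
#' fractions, and writes a SILVA-style FASTA, a sidecar taxonomy TSV and
#' a truth JSON into the output directory.
#'
#' `cfg$generate$plant` is a list of lists, each with fields `genus`,
#' `site` (start, end), `fraction` and `primer`.
#'
#' @param cfg A `run_config`.
#' @return Invisible list with `records`, `truth` and the written paths.
#' @export
run_generate <- function(cfg) {
  gen <- cfg$generate
  layout <- if (is.null(gen$v_regions)) {
    gene_layout(gen$total_len, p_cons = gen$p_cons, p_var = gen$p_var)
  } else {
    gene_layout(gen$total_len, as.data.frame(gen$v_regions),
                p_cons = gen$p_cons, p_var = gen$p_var)
  }
  backbone <- sample_backbone(layout, seed = cfg$seed)
  phyla <- cfg$phyla %||% paste0("Synthphylum", 1:4)
  genera <- cfg$genera %||% sprintf("Genussyn%02d", seq_len(gen$n_genera))
  log_msg("generating %d genera x %d sequences", length(genera),
          gen$n_per_genus)
  truth <- list(layout = list(total_len = layout$total_len,
                              p_cons = layout$p_cons,
                              p_var = layout$p_var,
                              variable_spans = layout_variable_spans(layout)),
                seed = cfg$seed, planted = list())
  recs <- vector("list", length(genera))
  for (i in seq_along(genera)) {
    lin <- c(domain = "Bacteria",
             phylum = phyla[((i - 1L) %% length(phyla)) + 1L],
             class = "Synthclass", order = "Synthorder",
             family = paste0(genera[i], "aceae"))
    recs[[i]] <- evolve_genus(backbone, gen$n_per_genus, layout,
                              seed = cfg$seed + i, genus = genera[i],
                              lineage = lin)
  }
  names(recs) <- genera
  for (pl in gen$plant %||% list()) {
    g <- pl$genus
    if (!g %in% genera) stop(sprintf("planted genus '%s' not generated", g),
                             call. = FALSE)
    planted <- plant_site_mismatches(recs[[g]], unlist(pl$site),
                                     pl$fraction, pl$primer,
                                     seed = cfg$seed + 10000L +
                                       match(g, genera))
    recs[[g]] <- planted$records
    truth$planted[[length(truth$planted) + 1L]] <- planted$truth
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(cfg$out_dir, "synthetic_16s.fasta")
  tsv <- file.path(cfg$out_dir, "synthetic_taxonomy.tsv")
  tj <- file.path(cfg$out_dir, "synthetic_truth.json")
  write_fasta_tax(records, fa)
  write_taxonomy_tsv(records, tsv)
  jsonlite::write_json(c(list(provenance = provenance(cfg)), truth), tj,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(records = records, truth = truth,
                 paths = c(fasta = fa, taxonomy = tsv, truth = tj)))
}

load_input_records <- function(cfg) {
  if (is.null(cfg$sequences)) {
    stop("configuration has no `sequences` FASTA path", call. = FALSE)
  }
  read_fasta_tax(cfg$sequences, dialect = cfg$dialect,
                 taxonomy = cfg$taxonomy)
}

load_input_primers <- function(cfg) {
  if (is.null(cfg$primers)) {
    stop("configuration has no `primers` table path", call. = FALSE)
  }
  read_primer_table(cfg$primers)
}

#' Run the coverage analysis
#'
#' Reads primers and sequences, deduplicates primer pairs, computes
#' phylum- and genus-rank coverage tables, applies the two-stage
#' candidate selection when the configuration names the four phyla and
#' twenty genera, and writes a long coverage TSV, wide taxa-by-primer
#' matrices (rows ordered by lineage) and a selection JSON.
#'
#' @param cfg A `run_config`.
#' @return Invisible list with the tables, the selection data.frame (or
#'   `NULL`) and written paths.
#' @export
run_coverage <- function(cfg) {
  pairs <- load_input_primers(cfg)
  dd <- dedupe_primer_pairs(pairs)
  if (dd$removed > 0L) {
    log_msg("removed %d duplicate primer pairs (%d unique)",
            dd$removed, nrow(dd$unique))
  }
  pairs <- dd$unique
  records <- load_input_records(cfg)
  prov <- provenance(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  tables <- list()
  long <- list()
  for (rank in c("phylum", "genus")) {
    log_msg("coverage at %s rank", rank)
    tbl <- coverage_table(pairs, records, rank, max_len = cfg$max_len,
                          min_length = cfg$min_length)
    tables[[rank]] <- tbl
    cells <- tbl$cells
    cells$rank <- rank
    cells$percent <- round(cells$percent, 1)
    long[[rank]] <- cells[, c("rank", "taxon", "set_id", "covered",
                              "denominator", "percent")]
    m <- coverage_matrix(tbl)
    m <- m[order_taxa_by_lineage(records, rank, rownames(m)), ,
           drop = FALSE]
    wide <- data.frame(taxon = rownames(m), round(m, 1),
                       check.names = FALSE)
    p <- file.path(cfg$out_dir, sprintf("coverage_matrix_%s.tsv", rank))
    write_tsv_prov(wide, p, prov)
    paths <- c(paths, p)
  }
  p_long <- file.path(cfg$out_dir, "coverage_long.tsv")
  write_tsv_prov(do.call(rbind, long), p_long, prov)
  paths <- c(paths, p_long)
  selection <- NULL
  if (!is.null(cfg$phyla) && !is.null(cfg$genera)) {
    selection <- select_candidates(tables$phylum, tables$genus,
                                   cfg$phyla, cfg$genera,
                                   cfg$phylum_threshold,
                                   cfg$genus_threshold, cfg$min_genera)
    p_sel <- file.path(cfg$out_dir, "selection.json")
    jsonlite::write_json(list(provenance = prov,
                              thresholds = list(
                                phylum = cfg$phylum_threshold,
                                genus = cfg$genus_threshold,
                                min_genera = cfg$min_genera),
                              results = selection),
                         p_sel, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p_sel)
  }
  invisible(list(tables = tables, selection = selection, paths = paths))
}

# Order taxon labels by their full lineage (domain, phylum, family,
# genus), the row order used for heatmap-style matrices.
order_taxa_by_lineage <- function(records, rank, taxa) {
  key <- vapply(taxa, function(tx) {
    r <- records[records[[rank]] == tx, , drop = FALSE][1L, ]
    paste(r$domain, r$phylum, r$family, r$genus, sep = ";")
  }, character(1))
  taxa[order(key, taxa)]
}

#' Run the variation analysis
#'
#' Per genus: QC by the 5' marker, subsample to `subsample_n`, align,
#' anchor-trim to the `frame_len`-column frame, per-column entropy,
#' variable/conserved segmentation.  Writes a long entropy TSV, a region
#' BED and a mean-profile TSV, and returns the profiles and annotations.
#'
#' @param cfg A `run_config`; `cfg$aligner` selects
#'   `"builtin_centerstar"` or `"external"` (with `cfg$aligner_path`).
#' @return Invisible list with `profiles`, `regions`, `summary` and
#'   written paths.
#' @export
run_variation <- function(cfg) {
  records <- load_input_records(cfg)
  prov <- provenance(cfg)
  genera <- cfg$genera %||% sort(unique(records$genus[records$genus != ""]))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  profiles <- list()
  regions <- list()
  for (g in genera) {
    sub <- records[records$genus == g, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning(sprintf("no sequences for genus '%s'; skipped", g))
      next
    }
    qc <- qc_marker_filter(sub, marker = cfg$marker)
    if (nrow(qc) < 2L) {
      warning(sprintf("genus '%s': fewer than 2 QC-passed sequences; skipped", g))
      next
    }
    if (nrow(qc) < 10L) {
      warning(sprintf("genus '%s': only %d QC-passed sequences (low n)",
                      g, nrow(qc)))
    }
    samp <- subsample(qc, n = cfg$subsample_n, seed = cfg$seed)
    log_msg("variation: %s (%d/%d sequences after QC/subsample)",
            g, nrow(samp), nrow(sub))
    msa <- build_msa(samp, method = cfg$aligner,
                     aligner = cfg$aligner_path)
    msa <- anchor_trim(msa, marker = cfg$marker,
                       frame_len = cfg$frame_len)
    profiles[[g]] <- entropy_profile(msa)
    regions[[g]] <- call_regions(profiles[[g]],
                                 threshold = cfg$entropy_threshold,
                                 merge_gap = cfg$merge_gap,
                                 min_len = cfg$min_region_len)
  }
  if (length(profiles) == 0L) {
    stop("no genus yielded an alignment; nothing to profile",
         call. = FALSE)
  }
  long <- do.call(rbind, lapply(names(profiles), function(g) {
    p <- profiles[[g]]
    data.frame(genus = g, column = seq_along(p$values),
               entropy_bits = round(p$values, 4), n_eff = p$n_eff,
               masked = p$masked, stringsAsFactors = FALSE)
  }))
  p_ent <- file.path(cfg$out_dir, "entropy_profiles.tsv")
  write_tsv_prov(long, p_ent, prov)
  p_bed <- file.path(cfg$out_dir, "regions.bed")
  write_regions_bed(regions, p_bed, prov)
  summ <- summarize_profiles(profiles)
  p_mean <- file.path(cfg$out_dir, "mean_profile.tsv")
  write_tsv_prov(data.frame(column = seq_along(summ$mean_profile),
                            mean_entropy_bits = round(summ$mean_profile, 4)),
                 p_mean, prov)
  p_idx <- file.path(cfg$out_dir, "entropy_index.tsv")
  write_tsv_prov(data.frame(genus = names(summ$index),
                            entropy_index = round(summ$index, 4)),
                 p_idx, prov)
  invisible(list(profiles = profiles, regions = regions, summary = summ,
                 paths = c(p_ent, p_bed, p_mean, p_idx)))
}

#' Run the binding-site analysis
#'
#' Aligns the (QC-filtered, subsampled) input community, anchor-trims,
#' derives the consensus, and for every primer pair locates the forward
#' site and the reverse-complemented reverse site, tallies per-position
#' residue counts, information content and incompatible fractions, and
#' flags 3'-end mismatch risk.  Primers whose site cannot be located are
#' reported as not found and the run continues.
#'
#' @param cfg A `run_config`.
#' @param max_mm Maximum consensus mismatches when locating a site.
#' @return Invisible list with `report` (per primer set) and written
#'   paths.
#' @export
run_binding <- function(cfg, max_mm = 3L) {
  pairs <- dedupe_primer_pairs(load_input_primers(cfg))$unique
  records <- load_input_records(cfg)
  prov <- provenance(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  qc <- qc_marker_filter(records, marker = cfg$marker)
  samp <- subsample(qc, n = cfg$subsample_n, seed = cfg$seed)
  log_msg("binding: aligning %d sequences", nrow(samp))
  msa <- build_msa(samp, method = cfg$aligner, aligner = cfg$aligner_path)
  msa <- anchor_trim(msa, marker = cfg$marker, frame_len = cfg$frame_len)
  cons <- consensus(msa, source = "community")
  report <- list()
  logo_rows <- list()
  for (i in seq_len(nrow(pairs))) {
    set_id <- pairs$set_id[i]
    entry <- list(set_id = set_id, region_tag = pairs$region_tag[i])
    for (ori in c("forward", "reverse")) {
      oligo <- pairs[[ori]][i]
      probe <- if (ori == "forward") oligo else reverse_complement(oligo)
      loc <- locate_site(probe, cons, max_mm = max_mm)
      if (is.null(loc)) {
        entry[[ori]] <- list(found = FALSE)
        log_msg("binding: %s %s primer site not found", set_id, ori)
        next
      }
      sm <- site_matrix(msa, loc$site_start, oligo, orientation = ori)
      mr <- mismatch_report(oligo, sm)
      entry[[ori]] <- list(
        found = TRUE, site_start = loc$site_start,
        consensus_mismatches = loc$mismatch_count,
        counts = unname(split(sm$counts, row(sm$counts))),
        info_bits = round(sm$info, 4),
        incompatible_fraction = round(mr$incompatible_fraction, 4),
        three_prime_flag = mr$three_prime_flag,
        flagged_positions = mr$flagged_positions,
        low_support = which(sm$low_support))
      heights <- sm$counts / pmax(1L, rowSums(sm$counts)) * sm$info
      logo_rows[[paste(set_id, ori)]] <- data.frame(
        set_id = set_id, oligo = ori,
        position = seq_len(nrow(sm$counts)),
        primer_base = rownames(sm$counts),
        round(heights, 4), info_bits = round(sm$info, 4),
        stringsAsFactors = FALSE)
    }
    report[[set_id]] <- entry
  }
  p_json <- file.path(cfg$out_dir, "binding.json")
  jsonlite::write_json(list(provenance = prov,
                            n_sequences = nrow(samp),
                            primer_sets = report),
                       p_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  p_logo <- file.path(cfg$out_dir, "logo_matrices.tsv")
  write_tsv_prov(do.call(rbind, logo_rows), p_logo, prov)
  invisible(list(report = report, paths = c(p_json, p_logo)))
}

#' Run the whole pipeline
#'
#' Generates the synthetic database (when no input FASTA is configured),
#' then runs coverage, variation and binding into `cfg$out_dir`.
#' Identical configuration and seed give byte-identical outputs.
#'
#' @param cfg A `run_config`.
#' @return Invisible named list of the stage results.
#' @export
run_all <- function(cfg) {
  if (is.null(cfg$sequences)) {
    gen <- run_generate(cfg)
    cfg$sequences <- gen$paths[["fasta"]]
    cfg$taxonomy <- gen$paths[["taxonomy"]]
    cfg$dialect <- "silva_header"
  } else {
    gen <- NULL
  }
  cov <- run_coverage(cfg)
  var <- run_variation(cfg)
  bind <- run_binding(cfg)
  invisible(list(generate = gen, coverage = cov, variation = var,
                 binding = bind))
}
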