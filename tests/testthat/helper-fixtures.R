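# Shared fixture builders; everything is generated in code.

# A short layout for fast tests: 200 nt, two variable blocks.
tiny_layout <- function(p_cons = 0, p_var = 0.5) {
  gene_layout(total_len = 200L,
              v_regions = data.frame(label = c("V1", "V2"),
                                     start = c(41L, 121L),
                                     end = c(80L, 160L)),
              p_cons = p_cons, p_var = p_var)
}

# Hand-build a coverage_table from a taxon x set_id percent data.frame.
fake_coverage_table <- function(rank, df, denominator = 100L) {
  df$covered <- as.integer(round(df$percent / 100 * denominator))
  df$denominator <- denominator
  taxa <- unique(df$taxon)
  structure(list(rank = rank,
                 cells = df[, c("taxon", "set_id", "covered",
                                "denominator", "percent")],
                 denominators = stats::setNames(rep(denominator,
                                                    length(taxa)), taxa)),
            class = "coverage_table")
}

# Alignment matrix from aligned strings.
aln_from <- function(...) {
  seqs <- c(...)
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- paste0("r", seq_along(seqs))
  m
}

random_iupac_string <- function(len) {
  paste(sample(c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N"), len, replace = TRUE),
        collapse = "")
}

# A random primer of length k with at most n_deg degenerate positions.
random_primer <- function(k, n_deg) {
  p <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
  nd <- sample.int(n_deg + 1L, 1L) - 1L
  if (nd > 0L) {
    idx <- sample.int(k, min(nd, k))
    p[idx] <- sample(c("R", "Y", "S", "W", "K", "M", "B", "D", "H",
                       "V", "N"), length(idx), replace = TRUE)
  }
  paste(p, collapse = "")
}

# Independent brute-force oracle: expand the degenerate primer into every
# concrete oligo and compare each template window against the pool
# (windows checked one by one so overlapping sites are all found).
brute_force_sites <- function(primer, template) {
  sets <- lapply(strsplit(primer, "", fixed = TRUE)[[1]], expand_iupac)
  pool <- do.call(expand.grid,
                  c(sets, list(stringsAsFactors = FALSE)))
  oligos <- unique(apply(pool, 1L, paste, collapse = ""))
  k <- nchar(primer)
  n <- nchar(template) - k + 1L
  if (n < 1L) return(integer(0))
  starts <- seq_len(n)
  windows <- substring(template, starts, starts + k - 1L)
  starts[windows %in% oligos]
}
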