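MARKER <- "AGAGTTTGATCATGGCTCAG"

test_that("5' marker QC retains anchored sequences only", {
  good <- paste0(MARKER, "CCCCGGGG")
  two_mm <- paste0("AGAGTTTGATCATGGCTGAC", "CCCC")   # 2 substitutions
  shifted <- paste0("AC", MARKER, "CCCC")             # starts at 3 (< 5)
  late <- paste0(strrep("T", 29), MARKER)             # starts at 30
  short <- substr(MARKER, 1, 10)
  recs <- tax_records(paste0("r", 1:5),
                      c(good, two_mm, shifted, late, short))
  kept <- qc_marker_filter(recs)
  expect_identical(kept$record_id, c("r1", "r2", "r3"))
  expect_identical(qc_marker_filter(recs, max_mismatch = 0L)$record_id,
                   c("r1", "r3"))
  expect_error(qc_marker_filter(recs[0, ]), "no input")
})

test_that("subsampling is seeded, uniform and a no-op for small inputs", {
  lay <- tiny_layout()
  recs <- evolve_genus(sample_backbone(lay, seed = 1), 150, lay,
                       seed = 2, genus = "Gx")
  s1 <- subsample(recs, 100, seed = 7)
  s2 <- subsample(recs, 100, seed = 7)
  expect_equal(nrow(s1), 100L)
  expect_identical(s1$record_id, s2$record_id)
  expect_false(identical(s1$record_id,
                         subsample(recs, 100, seed = 8)$record_id))
  small <- recs[1:31, ]
  expect_identical(subsample(small, 100, seed = 7), small)
  expect_equal(nrow(subsample(recs, 1, seed = 7)), 1L)
  # uniformity sanity: inclusion counts over many draws are flat
  counts <- integer(20)
  for (s in 1:200) {
    idx <- match(subsample(recs[1:20, ], 10, seed = s)$record_id,
                 recs$record_id[1:20])
    counts[idx] <- counts[idx] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("builtin center-star alignment follows the stated scoring", {
  # identical sequences: no gaps
  recs <- tax_records(c("a", "b", "c"), rep("ACGTACGT", 3))
  m <- build_msa(recs)
  expect_equal(ncol(m), 8L)
  expect_false(any(m == "-"))

  # "ACGT" vs "ACT": exhaustive check of all single-gap placements under
  # match +1 / mismatch -1 / gap -2 says AC-T (score 1) is optimal
  scores <- vapply(1:4, function(g) {
    padded <- append(strsplit("ACT", "")[[1]], "-", after = g - 1)
    sum(ifelse(padded == "-", -2,
               ifelse(padded == strsplit("ACGT", "")[[1]], 1, -1)))
  }, numeric(1))
  expect_equal(which.max(scores), 3L)
  m2 <- build_msa(tax_records(c("a", "b"), c("ACGT", "ACT")))
  expect_identical(paste(m2["b", ], collapse = ""), "AC-T")
  expect_identical(paste(m2["a", ], collapse = ""), "ACGT")

  expect_error(build_msa(recs[1, ]), "at least 2")
})

test_that("external aligner round-trips through FASTA", {
  lay <- tiny_layout(p_cons = 0.01, p_var = 0.2)
  recs <- evolve_genus(sample_backbone(lay, seed = 10), 6, lay,
                       seed = 11, genus = "Gext")
  m <- build_msa(recs, method = "external", aligner = "mafft")
  expect_identical(rownames(m), recs$record_id)
  expect_gte(ncol(m), 200L)
  degapped <- apply(m, 1, function(r) paste(r[r != "-"], collapse = ""))
  expect_identical(unname(degapped), recs$sequence)
  expect_error(build_msa(recs, method = "external",
                         aligner = "no_such_aligner_xyz"), "not found")
})

test_that("anchor trimming fixes frame position 1 at the marker", {
  lay <- tiny_layout()
  recs <- evolve_genus(sample_backbone(lay, seed = 20), 10, lay,
                       seed = 21, genus = "Gt")
  msa <- build_msa(recs)
  fr <- anchor_trim(msa, frame_len = 150L)
  expect_equal(ncol(fr), 150L)
  expect_equal(attr(fr, "frame_anchor"), 1L)
  expect_false(attr(fr, "padded"))
  expect_identical(paste(fr[1, 1:20], collapse = ""), MARKER)

  # marker deeper in the alignment: frame starts there
  shifted <- recs
  shifted$sequence <- paste0("TTTTTTTTTTT", shifted$sequence)
  fr2 <- anchor_trim(build_msa(shifted), frame_len = 150L)
  expect_equal(attr(fr2, "frame_anchor"), 12L)
  expect_identical(fr2[, 1:150], fr[, 1:150])

  # short alignment: right-padded with all-gap columns and flagged
  fr3 <- anchor_trim(msa, frame_len = 300L)
  expect_true(attr(fr3, "padded"))
  expect_equal(ncol(fr3), 300L)
  expect_true(all(fr3[, 250:300] == "-"))

  expect_error(anchor_trim(msa, marker = strrep("A", 30)), "anchor")
})

test_that("column entropy matches the closed forms", {
  expect_equal(shannon_entropy(c(A = 40)), 0)
  expect_equal(shannon_entropy(c(A = 25, C = 25, G = 25, T = 25)), 2)
  h <- shannon_entropy(c(A = 90, C = 10))
  expect_equal(round(h, 4), 0.4690)
  expect_lt(h, 0.5)           # classified conserved at the 0.5 threshold
  expect_equal(shannon_entropy(c(50, 0, 0, 50)), 1)
  expect_error(shannon_entropy(c(0, 0, 0, 0)), "no residues")
})

test_that("entropy profiles renormalise over non-gap residues and mask", {
  m <- aln_from("AAAT", "AAAT", "AA-T", "AA--", "CA--")
  ep <- entropy_profile(m)
  expect_equal(ep$n_eff, c(5L, 5L, 2L, 3L))
  # col 1: 4 A + 1 C; col 2 invariant; col 3 under half non-gap: masked
  expect_equal(ep$values[2], 0)
  expect_true(ep$masked[3])
  expect_true(is.na(ep$values[3]))
  expect_false(ep$masked[4])
  expect_equal(ep$values[4], 0)
  # ambiguity codes were masked to gap at alignment build time;
  # profile values always within [0, 2]
  expect_true(all(ep$values[!ep$masked] >= 0 & ep$values[!ep$masked] <= 2))
  # permutation invariance
  ep2 <- entropy_profile(m[sample(nrow(m)), , drop = FALSE])
  expect_equal(ep2$values, ep$values)
})

test_that("region calling follows the threshold/merge/min-length rule", {
  prof <- structure(list(values = c(0.1, 0.6, 0.7, 0.2, 0.8),
                         n_eff = rep(10L, 5), masked = rep(FALSE, 5),
                         frame_anchor = 1L), class = "entropy_profile")
  r0 <- call_regions(prof, merge_gap = 0L, min_len = 1L)
  v0 <- variable_spans(r0)
  expect_equal(v0$start, c(2L, 5L))
  expect_equal(v0$end, c(3L, 5L))
  r1 <- call_regions(prof, merge_gap = 1L, min_len = 1L)
  v1 <- variable_spans(r1)
  expect_equal(v1$start, 2L)
  expect_equal(v1$end, 5L)
  # all sub-threshold: no variable spans, one conserved span
  quiet <- structure(list(values = rep(0.2, 5), n_eff = rep(10L, 5),
                          masked = rep(FALSE, 5), frame_anchor = 1L),
                     class = "entropy_profile")
  rq <- call_regions(quiet, min_len = 1L)
  expect_equal(nrow(variable_spans(rq)), 0L)
  expect_identical(rq$label, "conserved")
  # min_len drops short merged runs
  r2 <- call_regions(prof, merge_gap = 0L, min_len = 2L)
  expect_equal(nrow(variable_spans(r2)), 1L)
  # determinism/idempotence and tiling
  r1b <- call_regions(prof, merge_gap = 1L, min_len = 1L)
  expect_identical(r1, r1b)
  expect_equal(r1$start[1], 1L)
  expect_equal(r1$end[nrow(r1)], 5L)
  expect_true(all(r1$start[-1] == r1$end[-nrow(r1)] + 1L))
})

test_that("profile summaries average unmasked columns", {
  p1 <- structure(list(values = c(0, 1), n_eff = c(4L, 4L),
                       masked = c(FALSE, FALSE), frame_anchor = 1L),
                  class = "entropy_profile")
  p2 <- structure(list(values = c(1, 0), n_eff = c(4L, 4L),
                       masked = c(FALSE, FALSE), frame_anchor = 1L),
                  class = "entropy_profile")
  s <- summarize_profiles(list(g1 = p1, g2 = p2))
  expect_equal(unname(s$mean_profile), c(0.5, 0.5))
  expect_equal(unname(s$index), c(0.5, 0.5))
  s2 <- summarize_profiles(list(g1 = p1, g2 = p1))
  expect_equal(unname(s2$mean_profile), p1$values)
  dead <- structure(list(values = c(NA_real_, NA_real_), n_eff = c(0L, 0L),
                         masked = c(TRUE, TRUE), frame_anchor = 1L),
                    class = "entropy_profile")
  expect_warning(s3 <- summarize_profiles(list(g1 = p1, bad = dead)),
                 "bad")
  expect_identical(names(s3$index), "g1")
  wide <- structure(list(values = rep(0, 3), n_eff = rep(1L, 3),
                         masked = rep(FALSE, 3), frame_anchor = 1L),
                    class = "entropy_profile")
  expect_error(summarize_profiles(list(g1 = p1, g3 = wide)), "g3")
})

test_that("canonical-region comparison reports detection and overlap", {
  prof <- structure(list(values = c(rep(0, 9), rep(1, 10), rep(0, 11)),
                         n_eff = rep(10L, 30), masked = rep(FALSE, 30),
                         frame_anchor = 1L), class = "entropy_profile")
  reg <- call_regions(prof, min_len = 5L)
  canon <- data.frame(label = c("V1", "V2"),
                      start = c(10L, 25L), end = c(19L, 30L))
  cmp <- compare_to_canonical(reg, canon, frame_len = 30L)
  expect_identical(cmp$detected, c(TRUE, FALSE))
  expect_equal(cmp$overlap_fraction, c(1, 0))
  none <- call_regions(structure(list(values = rep(0, 30),
                                      n_eff = rep(10L, 30),
                                      masked = rep(FALSE, 30),
                                      frame_anchor = 1L),
                                 class = "entropy_profile"))
  cmp2 <- compare_to_canonical(none, canon, frame_len = 30L)
  expect_equal(sum(cmp2$detected), 0L)
  expect_error(compare_to_canonical(reg, data.frame(label = "V9",
                                                    start = 20L,
                                                    end = 40L),
                                    frame_len = 30L), "outside")
})

test_that("planted variable blocks are recovered on a small layout", {
  lay <- tiny_layout(p_cons = 0, p_var = 0.5)
  recs <- evolve_genus(sample_backbone(lay, seed = 40), 60, lay,
                       seed = 41, genus = "Grec")
  msa <- anchor_trim(build_msa(recs), frame_len = 200L)
  reg <- call_regions(entropy_profile(msa))
  v <- variable_spans(reg)
  truth <- layout_variable_spans(lay)
  expect_equal(nrow(v), nrow(truth))
  expect_true(all(abs(v$start - truth$start) <= 5))
  expect_true(all(abs(v$end - truth$end) <= 5))
})
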