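test_that("degenerate matching uses subset semantics", {
  expect_true(matches_at("ARG", "AAGAGG", 1))
  expect_false(matches_at("ARG", "AAGAGG", 2))
  expect_true(matches_at("ACGT", "ACGT", 1))
  # a template N never matches a stricter primer position
  expect_false(matches_at("A", "N", 1))
  expect_true(matches_at("N", "R", 1))
  expect_error(matches_at("ACGT", "ACG", 1), "out of range")
  expect_error(matches_at("AC", "ACGT", 4), "out of range")
})

test_that("site scanning reports every matching window in ascending order", {
  expect_equal(find_sites("ARG", "AAGAGG"), c(1L, 4L))
  expect_equal(find_sites("TTTT", "AAAA"), integer(0))
  expect_equal(find_sites("N", "ACG"), 1:3)
  expect_equal(find_sites("ACGTT", "ACG"), integer(0))
  # overlapping sites are all reported
  expect_equal(find_sites("AA", "AAAA"), 1:3)
})

test_that("site scanning equals the brute-force expansion oracle", {
  withr::with_seed(101, {
    for (case in 1:1000) {
      primer <- random_primer(sample(3:12, 1), 3L)
      template <- paste(sample(c("A", "C", "G", "T"),
                               sample(10:60, 1), replace = TRUE),
                        collapse = "")
      expect_identical(find_sites(primer, template),
                       brute_force_sites(primer, template),
                       info = paste(primer, template))
    }
  })
})

test_that("amplicon prediction pairs forward and downstream reverse sites", {
  pair <- list(forward = "ACGT", reverse = "AAAA")
  rec <- list(record_id = "r1", sequence = "ACGTGGTTTT")
  hits <- predict_amplicons(pair, rec)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$fwd_start, 1L)
  expect_equal(hits$rev_end, 10L)
  expect_equal(hits$amplicon_len, 10L)

  # reverse-complement site upstream of the forward site: no amplicon
  rec2 <- list(record_id = "r2", sequence = "TTTTGGACGT")
  expect_equal(nrow(predict_amplicons(pair, rec2)), 0L)
  # no forward site at all
  rec3 <- list(record_id = "r3", sequence = "GGGGGGTTTT")
  expect_equal(nrow(predict_amplicons(pair, rec3)), 0L)
  # length cap and parameter validation
  expect_equal(nrow(predict_amplicons(pair, rec, max_len = 9L)), 0L)
  expect_error(predict_amplicons(pair, rec, max_len = 7L), "max_len")
})

test_that("strand symmetry: swapped primers on the rc template give the same amplicons", {
  withr::with_seed(21, {
    for (i in 1:20) {
      tmpl <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                    collapse = "")
      fwd <- substr(tmpl, 11, 18)
      rev <- reverse_complement(substr(tmpl, 51, 58))
      a <- predict_amplicons(list(forward = fwd, reverse = rev),
                             list(record_id = "x", sequence = tmpl))
      b <- predict_amplicons(list(forward = rev, reverse = fwd),
                             list(record_id = "x",
                                  sequence = reverse_complement(tmpl)))
      expect_equal(sort(a$amplicon_len), sort(b$amplicon_len))
    }
  })
})

test_that("coverage counts each amplified sequence once", {
  lay <- tiny_layout(p_cons = 0, p_var = 0.001)
  bb <- sample_backbone(lay, seed = 5)
  recs <- evolve_genus(bb, 10, lay, seed = 6, genus = "Blautia")
  fwd <- substr(bb$sequence, 1, 20)
  rev <- reverse_complement(substr(bb$sequence, 181, 200))
  pairs <- data.frame(set_id = "P1", region_tag = "V1",
                      forward = fwd, reverse = rev,
                      stringsAsFactors = FALSE)
  tbl <- coverage_table(pairs, recs, "genus")
  expect_s3_class(tbl, "coverage_table")
  expect_equal(tbl$cells$percent, 100)
  expect_equal(unname(tbl$denominators["Blautia"]), 10L)

  # destroy the site in 3 of 10: exactly 70.0 percent
  pl <- plant_site_mismatches(recs, c(1L, 20L), 0.3, fwd, seed = 9)
  tbl2 <- coverage_table(pairs, pl$records, "genus")
  expect_identical(tbl2$cells$percent, 70)
  expect_equal(pl$truth$expected_coverage, 70)

  # a record with two amplicons still increments the numerator by one
  two <- tax_records("t1", paste0(bb$sequence, bb$sequence),
                     "Bacteria;P;C;O;F;Blautia")
  expect_gt(nrow(predict_amplicons(list(forward = fwd, reverse = rev),
                                   list(record_id = "t1",
                                        sequence = two$sequence))), 1L)
  tbl3 <- coverage_table(pairs, two, "genus")
  expect_equal(tbl3$cells$covered, 1L)

  # records without the requested rank are excluded; none -> error
  norank <- tax_records("u1", bb$sequence)
  expect_error(coverage_table(pairs, norank, "genus"), "populated")
})

test_that("adding degeneracy to a primer never decreases coverage", {
  lay <- tiny_layout(p_cons = 0.02, p_var = 0.4)
  recs <- evolve_genus(sample_backbone(lay, seed = 31), 30, lay,
                       seed = 32, genus = "Dorea")
  fwd <- substr(recs$sequence[1], 41, 60)   # inside V1: imperfect matches
  rev <- reverse_complement(substr(recs$sequence[1], 181, 200))
  base_pairs <- data.frame(set_id = "P", region_tag = "V1",
                           forward = fwd, reverse = rev,
                           stringsAsFactors = FALSE)
  cov0 <- coverage_table(base_pairs, recs, "genus")$cells$percent
  withr::with_seed(33, {
    for (i in 1:10) {
      pos <- sample(nchar(fwd), 1)
      cur <- substr(fwd, pos, pos)
      widened <- primerscreen:::.BITS_TO_SYMBOL[
        bitwOr(primerscreen:::.IUPAC_BITS[[cur]],
               sample(c(1L, 2L, 4L, 8L), 1))]
      fwd2 <- fwd
      substr(fwd2, pos, pos) <- widened
      p2 <- base_pairs
      p2$forward <- fwd2
      cov1 <- coverage_table(p2, recs, "genus")$cells$percent
      expect_gte(cov1, cov0)
    }
  })
})

test_that("candidate selection applies both inclusive thresholds", {
  sets <- c("S1", "S2", "S3")
  phyla <- c("Actinobacteriota", "Bacteroidota", "Firmicutes",
             "Proteobacteria")
  genera <- paste0("G", 1:20)
  ptab <- fake_coverage_table("phylum", expand.grid(
    taxon = phyla, set_id = sets, stringsAsFactors = FALSE) |>
      transform(percent = c(70.0, 82.1, 91.0, 100.0,   # S1: passes
                            69.9, 95.0, 95.0, 95.0,    # S2: gate fails
                            70.0, 70.0, 70.0, 70.0)))  # S3: passes
  gcov <- c(rep(95, 5), rep(50, 15),    # S1: 5 genera at >=90
            rep(95, 20),                # S2: irrelevant, gate failed
            rep(95, 3), rep(89.9, 17))  # S3: only 3 qualify
  gtab <- fake_coverage_table("genus", expand.grid(
    taxon = genera, set_id = sets, stringsAsFactors = FALSE) |>
      transform(percent = gcov))
  sel <- select_candidates(ptab, gtab, phyla, genera)
  expect_identical(sel$candidate, c(TRUE, FALSE, FALSE))
  expect_identical(sel$phylum_pass, c(TRUE, FALSE, TRUE))
  expect_equal(sel$qualifying_genera, c(5L, 20L, 3L))
  expect_error(select_candidates(ptab, gtab, c(phyla, "Halobacterota"),
                                 genera), "Halobacterota")
})
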