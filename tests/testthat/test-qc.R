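tree <- toy_tree()

mk_records <- function(n, scores = 90) {
  tibble::tibble(query_id = paste0("q", seq_len(n)),
                 peptide = random_peptides(n),
                 score = rep_len(scores, n),
                 scan_ref = NA_character_, source_tool = "peaks",
                 is_decoy = FALSE)
}

mk_hit <- function(query_id, pident, qcov, bitscore = 40,
                   subject_id = "s1") {
  tibble::tibble(query_id = query_id, subject_id = subject_id,
                 pident = pident, qcov = qcov, raw_score = NA_real_,
                 bitscore = bitscore, evalue = 1e-4,
                 subject_taxids = list(8L), is_decoy_query = FALSE)
}

test_that("spectral categories partition queries by best-hit identity and
           coverage", {
  set.seed(51)
  rec <- mk_records(5)
  hits <- dplyr::bind_rows(
    mk_hit("q1", 100, 100),
    mk_hit("q2", 100, 85),
    mk_hit("q3", 92, 100),
    mk_hit("q4", 90, 80))
  qc <- classify_alignment_quality(rec, hits)
  expect_equal(as.character(qc$category),
               c("exact", "exact_tag", "aligned", "aligned_tag",
                 "unmatched"))
  # exhaustive and mutually exclusive over all queries
  expect_equal(nrow(qc), nrow(rec))
  expect_false(anyNA(qc$category))
})

test_that("the best hit is chosen by bitscore with documented tie-breaks", {
  set.seed(52)
  rec <- mk_records(1)
  hits <- dplyr::bind_rows(
    mk_hit("q1", 90, 100, bitscore = 50, subject_id = "worseScoreHigher"),
    mk_hit("q1", 100, 100, bitscore = 45, subject_id = "betterIdentity"))
  qc <- classify_alignment_quality(rec, hits)
  expect_equal(as.character(qc$category), "aligned")  # 50-bit hit wins
  # tie on bitscore: higher pident wins
  hits2 <- dplyr::bind_rows(
    mk_hit("q1", 90, 100, bitscore = 50),
    mk_hit("q1", 100, 100, bitscore = 50))
  expect_equal(as.character(classify_alignment_quality(rec,
                                                       hits2)$category),
               "exact")
})

test_that("rounded coverage values near 100 count as full coverage", {
  set.seed(53)
  rec <- mk_records(1)
  qc <- classify_alignment_quality(rec, mk_hit("q1", 100, 100 - 1e-9))
  expect_equal(as.character(qc$category), "exact")
})

test_that("PSM matching joins by peptide string or scan and reports status", {
  rec <- tibble::tibble(
    query_id = c("q1", "q2"), peptide = c("PEPTLDEK", "AAAGGGK"),
    score = c(95, 95), scan_ref = c("F1:1", "F1:2"),
    source_tool = "peaks", is_decoy = FALSE)
  # peptide-string join (PSM has no scans); modifications are stripped
  psm <- tibble::tibble(Peptide = "PEPTIDEK")
  out <- match_psms(rec[1:2, -4], psm)  # drop scan_ref usage via NA
  out <- match_psms(dplyr::mutate(rec, scan_ref = NA_character_), psm)
  expect_equal(out$db_status, c("matched", "not_detected"))
  # scan join preferred when both sides carry scans
  psm2 <- tibble::tibble(Peptide = "OTHERPEP", Scan = "F1:2")
  out2 <- match_psms(rec, psm2)
  expect_equal(out2$db_status, c("not_detected", "matched"))
  # no PSM table -> unknown
  expect_equal(match_psms(rec, NULL)$db_status, c("unknown", "unknown"))
  expect_error(match_psms(rec, tibble::tibble(Seq = "X")), "Peptide")
})

test_that("high-quality matched fraction counts only records above the
           threshold", {
  rec <- tibble::tibble(score = c(rep(95, 10), rep(70, 5)),
                        db_status = c(rep("matched", 8),
                                      rep("not_detected", 7)))
  expect_equal(high_quality_matched_fraction(rec, 90), 0.8)
  expect_equal(high_quality_matched_fraction(
    dplyr::mutate(rec, db_status = "matched"), 90), 1.0)
  expect_warning(r <- high_quality_matched_fraction(rec, 99.5),
                 "undefined")
  expect_true(is.na(r))
})

test_that("PSM peptides map to protein taxa with CON reduction of
           multi-protein peptides", {
  db <- build_reference_db(tibble::tibble(
    accession = c("A1", "A2", "B1"), taxid = c(8L, 9L, 14L),
    seq = c("M", "M", "M")))
  psm <- tibble::tibble(Peptide = c("PEPK", "GGGR"),
                        Accession = c("A1;A2", "B1"))
  out <- map_psm_taxa(psm, db, tree)
  expect_equal(out$genus[out$peptide == "PEPK"], "Bacillus")  # CON of 8,9
  expect_true(is.na(out$species[out$peptide == "PEPK"]))
  expect_equal(out$species[out$peptide == "GGGR"], "Listeria quarta")
})

test_that("coverage report set algebra and per-rank normalization hold", {
  dn <- dplyr::bind_cols(
    tibble::tibble(peptide = c("AAA", "BBB", "CCC")),
    dplyr::bind_rows(tax_lineage(tree, 8L)[-1], tax_lineage(tree, 9L)[-1],
                     tax_lineage(tree, 14L)[-1]))
  db <- dplyr::bind_cols(
    tibble::tibble(peptide = c("BBB", "DDD")),
    dplyr::bind_rows(tax_lineage(tree, 9L)[-1], tax_lineage(tree, 20L)[-1]))
  rep <- db_coverage_report(dn, db)
  dn_only <- rep[rep$set == "DN_only", ]
  expect_setequal(unique(dn_only$taxon[dn_only$rank == "family"]),
                  c("Bacillaceae", "Listeriaceae"))
  db_only <- rep[rep$set == "DB_only" & rep$rank == "family", ]
  expect_equal(db_only$taxon, "Enteraceae")
  # fractions sum to 1 within every set x rank
  sums <- tapply(rep$fraction, list(rep$set, rep$rank), sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9))
  # identical inputs leave both exclusive sets empty
  rep2 <- db_coverage_report(dn, dn)
  expect_equal(nrow(rep2[rep2$set %in% c("DN_only", "DB_only"), ]), 0)
  expect_warning(db_coverage_report(dn, NULL), "omitted")
})
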