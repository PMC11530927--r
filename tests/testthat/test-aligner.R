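toy_db <- function() {
  build_reference_db(tibble::tibble(
    accession = c("P1", "P2", "P3"),
    taxid = c(8L, 9L, 20L),
    seq = c("MAAAPEPTLDEKGGGSVVKTTTR", "MKKKPEPTLDEAGGGR",
            "MWWWYYYHHHFFFRDDDEEK")))
}

test_that("reference databases derive taxids from common header dialects", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">UniRef100_A0A1 Uncharacterized TaxID=562 RepID=X",
               "PEPTIDESEQ",
               ">sp|P12345|NAME Protein OS=Escherichia coli OX=562 GN=abc",
               "ANOTHERSEQ"), fa)
  db <- build_reference_db(fa)
  expect_equal(db$taxid, c(562L, 562L))
  expect_false(any(grepl("I", db$seq)))  # L-normalized

  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">acc1 no taxid here", "PEPTIDE", ">acc2 none", "PEPTIDE"),
             fa2)
  expect_error(build_reference_db(fa2), "TaxID")
  map <- tibble::tibble(accession = c("acc1", "acc2"), taxid = c(1L, 2L))
  db2 <- build_reference_db(fa2, taxid_map = map)
  expect_equal(db2$taxid, c(1L, 2L))
})

test_that("identical sequences align at full identity and coverage", {
  db <- toy_db()
  q <- tibble::tibble(query_id = "q1", peptide = "PEPTLDEKGG",
                      is_decoy = FALSE)
  h <- align_peptides(q, db, align_params())
  top <- h[h$subject_id == "P1", ]
  expect_equal(top$pident, 100)
  expect_equal(top$qcov, 100)
  expect_equal(top$subject_taxids[[1]], 8L)
})

test_that("internal raw scores equal the brute-force DP oracle", {
  mat <- denovotax:::get_substitution_matrix("PAM70")
  db_seqs <- c("MAAAPEPTLDEKGG", "WWYYHHFFKRDDEE")
  set.seed(21)
  for (i in 1:40) {
    q <- paste(sample(denovotax:::ALPHABET19, sample(6:12, 1), TRUE),
               collapse = "")
    s <- db_seqs[1 + i %% 2]
    db <- build_reference_db(tibble::tibble(accession = "S", taxid = 1L,
                                            seq = s))
    h <- align_peptides(
      tibble::tibble(query_id = "q", peptide = q, is_decoy = FALSE), db,
      align_params(min_pident = 0, min_qcov = 0), exhaustive = TRUE)
    got <- if (nrow(h) == 0) 0 else max(h$raw_score)
    want <- oracle_local_score(q, s, mat, 2, 4)
    if (want > 0) expect_equal(got, want) else expect_equal(nrow(h), 0)
  }
})

test_that("alignment score is symmetric for symmetric matrices", {
  mat <- denovotax:::get_substitution_matrix("PAM70")
  set.seed(22)
  for (i in 1:10) {
    a <- paste(sample(denovotax:::ALPHABET19, 10, TRUE), collapse = "")
    b <- paste(sample(denovotax:::ALPHABET19, 12, TRUE), collapse = "")
    expect_equal(oracle_local_score(a, b, mat, 2, 4),
                 oracle_local_score(b, a, mat, 2, 4))
  }
})

test_that("bitscore filtering is inclusive at the threshold", {
  hits <- tibble::tibble(
    query_id = c("a", "b", "c"), subject_id = "s",
    pident = 100, qcov = 100, raw_score = NA_real_,
    bitscore = c(24.9, 25, 26), evalue = 1e-3,
    subject_taxids = list(1L, 1L, 1L), is_decoy_query = FALSE)
  kept <- filter_hits(hits, 25)
  expect_equal(kept$query_id, c("b", "c"))
  expect_equal(nrow(filter_hits(hits[0, ], 25)), 0)
})

test_that("blast tabular parsing recovers decoys, taxids, malformed rows", {
  f <- tempfile()
  writeLines(c(
    "row0\tP1\t100.0\t8\t0\t0\t1\t8\t4\t11\t1e-05\t27.3\t100.0\t562",
    "row5_DECOY\tP2\t87.5\t8\t1\t0\t1\t8\t4\t11\t2e-03\t21.0\t100.0\t562;623",
    "rowX\tP3\tnot_a_number\t8\t0\t0\t1\t8\t4\t11\t1e-05\t19.0\t100.0\t562"),
    f)
  expect_message(h <- parse_hits(f), "malformed")
  expect_equal(nrow(h), 2)
  expect_equal(h$bitscore[1], 27.3)
  expect_true(h$is_decoy_query[2])
  expect_equal(h$subject_taxids[[2]], c(562L, 623L))
})

test_that("missing taxid columns are resolved through the accession map", {
  f <- tempfile()
  writeLines("row0\tP1\t100.0\t8\t0\t0\t1\t8\t4\t11\t1e-05\t27.3", f)
  h <- parse_hits(f, taxid_map = toy_db())
  expect_equal(h$subject_taxids[[1]], 8L)
})

test_that("the external aligner command carries the short-peptide settings", {
  args <- run_diamond("q.fasta", "db.dmnd", "o.tsv", dry_run = TRUE)
  expect_true(all(c("PAM70", "--gapopen", "--gapextend", "--id",
                    "--query-cover", "ctg") %in% args))
  expect_equal(args[which(args == "--gapopen") + 1], "2")
  expect_equal(args[which(args == "--gapextend") + 1], "4")
  expect_equal(args[which(args == "--id") + 1], "85")
  expect_equal(args[which(args == "--masking") + 1], "0")
})

test_that("empty query input is rejected before any invocation", {
  expect_error(align_peptides(tibble::tibble(query_id = character(),
                                             peptide = character()),
                              toy_db()), "no query")
  f <- tempfile(fileext = ".fasta")
  expect_error(run_diamond(f, "db", "out"), "missing or empty")
})

test_that("Karlin-Altschul parameters reproduce published BLOSUM62 values", {
  rr <- c(A = 78.05, R = 51.29, N = 44.87, D = 53.64, C = 19.25, Q = 42.64,
          E = 62.95, G = 73.77, H = 21.99, I = 51.42, L = 90.19, K = 57.44,
          M = 22.43, F = 38.56, P = 52.03, S = 71.20, T = 58.41, W = 13.30,
          Y = 32.16, V = 64.41)
  kp <- karlin_params("BLOSUM62", rr / sum(rr))
  expect_equal(kp$lambda, 0.3176, tolerance = 1e-3)
  expect_equal(kp$K, 0.134, tolerance = 0.02)
})
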