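tree <- toy_tree()

# Build an LCA-result tibble from (taxid, n, decoy) specs.
lca_from_counts <- function(spec) {
  rows <- purrr::pmap(spec, function(taxid, n, decoy) {
    lin <- tax_lineage(tree, rep(taxid, n))
    dplyr::bind_cols(
      tibble::tibble(query_id = sprintf("q%s_%d", taxid, seq_len(n)),
                     is_decoy_query = decoy, method = "W", n_hits = 1L),
      lin[-1])
  })
  out <- dplyr::bind_rows(rows)
  out$query_id <- make.unique(out$query_id)
  out
}

test_that("composition pools sub-freq_cut taxa and conserves fractions", {
  lca <- lca_from_counts(tibble::tibble(
    taxid = c(8L, 11L, 14L), n = c(90, 10, 4), decoy = FALSE))
  comp <- compose(lca, rank = "genus", freq_cut = 5)
  expect_setequal(comp$taxon, c("Bacillus", "Geobacillus", "other"))
  expect_equal(comp$n_peptides[comp$taxon == "other"], 4)  # Listeria pooled
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-9)
  fam <- compose(lca, rank = "family", freq_cut = 5)
  expect_equal(fam$fraction[fam$taxon == "Bacillaceae"], 100 / 104)

  # counts 90/10 -> fractions .9/.1 with nothing pooled
  lca2 <- lca_from_counts(tibble::tibble(
    taxid = c(8L, 14L), n = c(90, 10), decoy = FALSE))
  comp2 <- compose(lca2, rank = "family", freq_cut = 5)
  expect_equal(sort(comp2$fraction), c(0.1, 0.9))
})

test_that("composition is invariant to input row order", {
  lca <- lca_from_counts(tibble::tibble(
    taxid = c(8L, 11L, 14L, 20L), n = c(40, 30, 20, 10), decoy = FALSE))
  comp_a <- compose(lca, rank = "family", freq_cut = 5)
  comp_b <- compose(lca[sample(nrow(lca)), ], rank = "family", freq_cut = 5)
  expect_equal(tibble::as_tibble(comp_a), tibble::as_tibble(comp_b))
})

test_that("decoys drive the match rate but never the fractions", {
  lca <- lca_from_counts(tibble::tibble(
    taxid = c(8L, 20L, 14L), n = c(50, 10, 30), decoy = c(FALSE, FALSE,
                                                          TRUE)))
  comp <- compose(lca, rank = "family", freq_cut = 5, n_decoy_total = 60)
  expect_equal(attr(comp, "decoy_match_rate"), 30 / 60)
  expect_equal(attr(comp, "n_classified"), 60)
  expect_false("Listeriaceae" %in% comp$taxon)  # decoy-only taxon

  all_decoy <- lca_from_counts(tibble::tibble(taxid = 8L, n = 5,
                                              decoy = TRUE))
  expect_warning(comp0 <- compose(all_decoy, rank = "family"),
                 "no classified")
  expect_equal(nrow(comp0), 0)
  expect_equal(attr(comp0, "decoy_match_rate"), 1)
})

test_that("spearman comparison matches a rank-then-correlate oracle", {
  lca_a <- lca_from_counts(tibble::tibble(
    taxid = c(8L, 11L, 14L, 20L), n = c(40, 30, 20, 10), decoy = FALSE))
  comp_a <- compose(lca_a, rank = "species", freq_cut = 0)
  expect_equal(spearman_compare(comp_a, comp_a), 1)

  lca_b <- lca_from_counts(tibble::tibble(
    taxid = c(8L, 11L, 14L, 20L), n = c(10, 20, 30, 40), decoy = FALSE))
  comp_b <- compose(lca_b, rank = "species", freq_cut = 0)
  expect_equal(spearman_compare(comp_a, comp_b), -1)

  # random tables vs mid-rank + Pearson oracle
  set.seed(41)
  for (i in 1:10) {
    na <- sample(5:40, 4)
    nb <- sample(5:40, 4)
    ca <- compose(lca_from_counts(tibble::tibble(
      taxid = c(8L, 11L, 14L, 20L), n = na, decoy = FALSE)),
      rank = "species", freq_cut = 0)
    cb <- compose(lca_from_counts(tibble::tibble(
      taxid = c(8L, 11L, 14L, 20L), n = nb, decoy = FALSE)),
      rank = "species", freq_cut = 0)
    m <- dplyr::full_join(tibble::as_tibble(ca)[c("taxon", "n_peptides")],
                          tibble::as_tibble(cb)[c("taxon", "n_peptides")],
                          by = "taxon")
    oracle <- cor(rank(m$n_peptides.x), rank(m$n_peptides.y))
    expect_equal(spearman_compare(ca, cb), oracle)
  }

  tiny <- compose(lca_from_counts(tibble::tibble(
    taxid = 8L, n = 10, decoy = FALSE)), rank = "species", freq_cut = 0)
  expect_warning(r <- spearman_compare(tiny, tiny), "fewer than 3")
  expect_true(is.na(r))
})

test_that("taxon sequence extraction honors rank, exclusions and options", {
  db <- build_reference_db(tibble::tibble(
    accession = c("A1", "A2", "B1", "C1"),
    taxid = c(8L, 9L, 11L, 14L),
    seq = c("MPEPK", "MGGGR", "MWWWK", "MYYYR")))
  out <- extract_taxon_sequences(db, tree, "Bacillaceae", rank = "family")
  expect_setequal(out$accession, c("A1", "A2", "B1"))
  out2 <- extract_taxon_sequences(db, tree, "Bacillaceae", rank = "family",
                                  exclude = "A2")
  expect_false("A2" %in% out2$accession)
  out3 <- extract_taxon_sequences(db, tree, "Bacillus", rank = "genus",
                                  add_decoys = TRUE, seed = 1,
                                  queries = tibble::tibble(
                                    query_id = "q1", peptide = "PEPK"))
  expect_setequal(out3$accession, c("A1", "A2", "A1_DECOY", "A2_DECOY",
                                    "q1"))
  expect_error(extract_taxon_sequences(db, tree, character(0)), "empty")
  expect_warning(extract_taxon_sequences(db, tree, "Nosuchaceae"),
                 "no sequences")
})

test_that("database complementation deduplicates and stays a superset", {
  base <- tibble::tibble(accession = paste0("m", 1:10),
                         seq = vapply(1:10, function(i)
                           paste(sample(denovotax:::ALPHABET19, 30, TRUE),
                                 collapse = ""), character(1)))
  extra <- tibble::tibble(accession = paste0("x", 1:5),
                          seq = vapply(1:5, function(i)
                            paste(sample(denovotax:::ALPHABET19, 30, TRUE),
                                  collapse = ""), character(1)))
  merged <- suppressMessages(complement_db(base, extra))
  expect_equal(nrow(merged), 15)
  expect_true(all(base$seq %in% merged$seq))      # strict superset
  same <- suppressMessages(complement_db(base, base))
  expect_equal(nrow(same), 10)                    # dedup on identical input
})
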