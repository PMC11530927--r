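tree <- toy_tree()

test_that("taxdump round trip preserves lineages; broken dumps error", {
  d <- tempfile()
  write_taxdump(tree, d)
  tree2 <- load_taxdump(d)
  expect_identical(tax_lineage(tree, toy_species),
                   tax_lineage(tree2, toy_species))
  lin <- tax_lineage(tree2, 20L)
  expect_equal(lin$species, "Escherichium quintum")
  expect_true(all(!is.na(unlist(lin[paste0(RANKS7, "_taxid")]))))

  unlink(file.path(d, "names.dmp"))
  expect_error(load_taxdump(d), "names.dmp")

  # a two-node parent cycle must be rejected
  expect_error(tax_tree(parent = c("1" = 1L, "2" = 3L, "3" = 2L),
                        rank = c("1" = "no rank", "2" = "genus",
                                 "3" = "genus"),
                        name = c("1" = "root", "2" = "a", "3" = "b")),
               "cycle")
})

test_that("a lineage table reconstructs an equivalent taxonomy", {
  lin <- tax_lineage(tree, toy_species)
  tab <- lin[c("taxid", RANKS7)]
  f <- tempfile(fileext = ".tsv")
  readr::write_tsv(tab, f)
  tree2 <- load_taxdump(f)
  lin2 <- tax_lineage(tree2, toy_species)
  expect_equal(lin2[RANKS7], lin[RANKS7])   # names match rank for rank
  expect_equal(lin2$species_taxid, lin$species_taxid)
})

test_that("unknown taxids yield empty lineages", {
  lin <- tax_lineage(tree, c(8L, 999L))
  expect_equal(lin$family, c("Bacillaceae", NA))
})

test_that("conventional LCA stops at the deepest shared rank", {
  lin <- tax_lineage(tree, c(8L, 9L))        # same genus, different species
  res <- lca_conventional(lin)
  expect_equal(res$genus, "Bacillus")
  expect_true(is.na(res$species))

  lin2 <- tax_lineage(tree, c(8L, 11L))      # same family, different genus
  res2 <- lca_conventional(lin2)
  expect_equal(res2$family, "Bacillaceae")
  expect_true(is.na(res2$genus))

  single <- tax_lineage(tree, 14L)           # identity on one lineage
  expect_equal(lca_conventional(single)$species, "Listeria quarta")

  mixed <- tax_lineage(tree, c(8L, 20L))     # diverge at phylum
  res3 <- lca_conventional(mixed)
  expect_equal(res3$superkingdom, "Bacteria")
  expect_true(is.na(res3$phylum))
})

test_that("weighted LCA keeps the minimal cumulative prefix", {
  lin <- tax_lineage(tree, c(8L, 20L))
  lin$taxid <- c(8L, 20L)
  # dominant taxon crosses the 0.6 cutoff alone
  res <- lca_weighted(lin, c("8" = 9, "20" = 1), 0.6)
  expect_equal(res$species, "Bacillus primus")
  # equal weights: first taxon reaches 0.5 < 0.6, both retained -> LCA
  res2 <- lca_weighted(lin, c("8" = 1, "20" = 1), 0.6)
  expect_equal(res2$superkingdom, "Bacteria")
  expect_true(is.na(res2$phylum))
  # cutoff 1 equals the conventional LCA
  res3 <- lca_weighted(lin, c("8" = 9, "20" = 1), 1)
  expect_equal(res3, lca_conventional(lin))
})

test_that("bitscore LCA assigns by share per rank and stops cleanly", {
  hits <- tax_lineage(tree, c(8L, 11L))      # two genera, one family
  hits$bitscore <- c(60, 30)
  res <- lca_bitscore(hits, 0.6)             # share 0.667 > 0.6
  expect_equal(res$genus, "Bacillus")
  hits$bitscore <- c(50, 50)                 # tie: genus blocked,
  res2 <- lca_bitscore(hits, 0.6)            # family still resolves
  expect_true(is.na(res2$genus))
  expect_equal(res2$family, "Bacillaceae")
})

test_that("LCA results are invariant to hit ordering", {
  set.seed(31)
  for (i in 1:20) {
    hits <- random_hit_set(tree, toy_species)
    perm <- hits[sample(nrow(hits)), ]
    w <- setNames(sample(1:10, 5), as.character(toy_species))
    expect_equal(lca_conventional(hits), lca_conventional(perm))
    expect_equal(lca_weighted(hits, w, 0.6), lca_weighted(perm, w, 0.6))
    expect_equal(lca_bitscore(hits, 0.6), lca_bitscore(perm, 0.6))
  }
})

test_that("assign_lca processes targets and decoys and excludes decoys from
           global weights", {
  hits <- tibble::tibble(
    query_id = c("q1", "q1", "q2", "q3_DECOY", "q3_DECOY"),
    subject_id = paste0("s", 1:5),
    pident = 100, qcov = 100, raw_score = NA_real_,
    bitscore = c(40, 35, 50, 30, 28), evalue = 1e-4,
    subject_taxids = list(8L, 9L, 8L, 20L, 14L),
    is_decoy_query = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  res <- assign_lca(hits, tree, lca_params("W", weight_cutoff = 0.6))
  expect_equal(nrow(res), 3)
  expect_equal(sort(res$query_id), c("q1", "q2", "q3_DECOY"))
  # q2 has one hit: full lineage of species 8
  expect_equal(res$species[res$query_id == "q2"], "Bacillus primus")
  # q1: global weights favor taxon 8 (2 target hits vs 1), 2/3 >= 0.6
  expect_equal(res$species[res$query_id == "q1"], "Bacillus primus")
  # the decoy query is flagged and still classified from its own hits
  expect_true(res$is_decoy_query[res$query_id == "q3_DECOY"])
  # decoy taxa got no global weight: LCA over both with uniform fallback
  expect_equal(res$superkingdom[res$query_id == "q3_DECOY"], "Bacteria")
  expect_true(is.na(res$phylum[res$query_id == "q3_DECOY"]))

  # single-hit queries give the same lineage under all three methods
  one <- hits[3, ]
  for (m in c("CON", "W", "BIT")) {
    r <- assign_lca(one, tree, lca_params(m))
    expect_equal(r$species, "Bacillus primus")
  }
})

test_that("hits with unknown taxids are dropped with a message", {
  hits <- tibble::tibble(
    query_id = "q1", subject_id = "s1", pident = 100, qcov = 100,
    raw_score = NA_real_, bitscore = 40, evalue = 1e-4,
    subject_taxids = list(c(8L, 777L)), is_decoy_query = FALSE)
  expect_message(res <- assign_lca(hits, tree, lca_params("CON")),
                 "absent from the taxonomy")
  expect_equal(res$species, "Bacillus primus")
})
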