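# Shared fixture builders (all generated in code; no files shipped).

# A small fixed taxonomy: 2 phyla, 3 families, 5 species.
toy_tree <- function() {
  edges <- list(
    #    id parent rank             name
    list(1L, 1L, "no rank", "root"),
    list(2L, 1L, "superkingdom", "Bacteria"),
    list(3L, 2L, "phylum", "Firmibacterota"),
    list(4L, 3L, "class", "Bacillia"),
    list(5L, 4L, "order", "Bacillales"),
    list(6L, 5L, "family", "Bacillaceae"),
    list(7L, 6L, "genus", "Bacillus"),
    list(8L, 7L, "species", "Bacillus primus"),
    list(9L, 7L, "species", "Bacillus secundus"),
    list(10L, 6L, "genus", "Geobacillus"),
    list(11L, 10L, "species", "Geobacillus tertius"),
    list(12L, 5L, "family", "Listeriaceae"),
    list(13L, 12L, "genus", "Listeria"),
    list(14L, 13L, "species", "Listeria quarta"),
    list(15L, 2L, "phylum", "Proteobacterota"),
    list(16L, 15L, "class", "Gammania"),
    list(17L, 16L, "order", "Enterales"),
    list(18L, 17L, "family", "Enteraceae"),
    list(19L, 18L, "genus", "Escherichium"),
    list(20L, 19L, "species", "Escherichium quintum")
  )
  ids <- vapply(edges, function(e) as.character(e[[1]]), character(1))
  tax_tree(
    parent = setNames(vapply(edges, function(e) e[[2]], integer(1)), ids),
    rank = setNames(vapply(edges, function(e) e[[3]], character(1)), ids),
    name = setNames(vapply(edges, function(e) e[[4]], character(1)), ids)
  )
}

toy_species <- c(8L, 9L, 11L, 14L, 20L)

# Write a PEAKS-dialect de novo CSV.
write_peaks_csv <- function(peptides, alc, path = tempfile(fileext = ".csv"),
                            ppm = NULL, area = NULL, scan = NULL) {
  n <- length(peptides)
  df <- tibble::tibble(
    Peptide = peptides,
    `ALC (%)` = alc,
    ppm = ppm %||% round(stats::rnorm(n, 0, 4), 1),
    Area = area %||% rep(1e5, n),
    Scan = scan %||% sprintf("F2:%d", seq_len(n))
  )
  readr::write_csv(df, path, progress = FALSE)
  path
}

# Random hit sets over the toy tree for LCA property tests: n_hits rows of
# (taxid, bitscore) with lineages attached.
random_hit_set <- function(tree, species, n_hits = NULL) {
  n <- n_hits %||% sample(1:6, 1)
  taxid <- sample(species, n, replace = TRUE)
  hits <- tax_lineage(tree, taxid)
  hits$bitscore <- round(stats::runif(n, 26, 80), 1)
  hits
}

`%||%` <- function(a, b) if (is.null(a)) b else a
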