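# Community composition from per-peptide consensus taxonomies, with
# decoy-based false-positive control; construction and complementation of
# reference databases from identified taxa.

#' Aggregate LCA results into a community composition
#'
#' Counts classified target peptides per taxon at the chosen rank. Taxa with
#' fewer than `freq_cut` peptides are pooled into `"other"` (so fractions
#' stay conserved); fractions are computed over classified target peptides.
#' The decoy retained-alignment rate is reported alongside as the
#' false-positive control: the fraction of decoy queries that obtained at
#' least one retained alignment.
#'
#' @param lca_results Tibble from [assign_lca()] (targets and decoys).
#' @param rank Ladder rank to report (default `"family"`).
#' @param freq_cut Minimum peptide count for a taxon to be reported
#'   (default 5).
#' @param n_decoy_total Total number of decoy queries submitted to alignment;
#'   defaults to the decoy queries present in `lca_results` (i.e. those with
#'   retained alignments), which overestimates the rate — pass the true
#'   submitted count for a calibrated rate.
#' @return A `composition_table`: tibble (`taxon`, `taxid`, `n_peptides`,
#'   `fraction`) with attributes `rank`, `freq_cut`, `n_classified`,
#'   `n_unclassified`, `decoy_match_rate`.
#' @export
compose <- function(lca_results, rank = "family", freq_cut = 5,
                    n_decoy_total = NULL) {
  stopifnot(rank %in% TAX_RANKS, freq_cut >= 0)
  targets <- lca_results[!lca_results$is_decoy_query, , drop = FALSE]
  decoys <- lca_results[lca_results$is_decoy_query, , drop = FALSE]
  n_decoy_total <- n_decoy_total %||% nrow(decoys)
  decoy_match_rate <- if (n_decoy_total > 0) {
    sum(decoys$n_hits >= 1) / n_decoy_total
  } else NA_real_

  classified <- targets[!is.na(targets[[rank]]), , drop = FALSE]
  n_classified <- nrow(classified)
  n_unclassified <- nrow(targets) - n_classified
  if (n_classified == 0) {
    warning("no classified peptides at rank ", rank)
    tab <- tibble::tibble(taxon = character(), taxid = integer(),
                          n_peptides = integer(), fraction = numeric())
  } else {
    counts <- classified |>
      dplyr::count(taxon = .data[[rank]],
                   taxid = .data[[paste0(rank, "_taxid")]],
                   name = "n_peptides") |>
      dplyr::arrange(dplyr::desc(.data$n_peptides), .data$taxon)
    low <- counts$n_peptides < freq_cut
    tab <- counts[!low, , drop = FALSE]
    if (any(low)) {
      tab <- dplyr::bind_rows(tab, tibble::tibble(
        taxon = "other", taxid = NA_integer_,
        n_peptides = sum(counts$n_peptides[low])))
    }
    tab$fraction <- tab$n_peptides / n_classified
  }
  structure(tab, class = c("composition_table", class(tab)),
            rank = rank, freq_cut = freq_cut, n_classified = n_classified,
            n_unclassified = n_unclassified,
            decoy_match_rate = decoy_match_rate)
}

#' @export
print.composition_table <- function(x, ...) {
  cat("Community composition at rank '", attr(x, "rank"), "' (freq_cut ",
      attr(x, "freq_cut"), ")\n", attr(x, "n_classified"), " classified / ",
      attr(x, "n_unclassified"), " unclassified peptides; decoy match rate ",
      format(attr(x, "decoy_match_rate"), digits = 3), "\n", sep = "")
  NextMethod()
}

#' Compare two compositions by Spearman rank correlation
#'
#' Taxa of both tables are unioned (absent taxa counted 0; the `"other"`
#' pool is excluded) and the peptide counts are rank-correlated.
#'
#' @param comp_a,comp_b `composition_table`s at the same rank.
#' @param use `"n_peptides"` (default) or `"fraction"` — identical ranks
#'   either way within one table; counts keep ties comparable across tables.
#' @return Spearman's rho, or `NA` (with a warning) when fewer than 3 taxa
#'   are available.
#' @export
spearman_compare <- function(comp_a, comp_b, use = "n_peptides") {
  stopifnot(identical(attr(comp_a, "rank"), attr(comp_b, "rank")))
  a <- comp_a[comp_a$taxon != "other", c("taxon", use)]
  b <- comp_b[comp_b$taxon != "other", c("taxon", use)]
  m <- dplyr::full_join(a, b, by = "taxon", suffix = c("_a", "_b"))
  m[is.na(m)] <- 0
  if (nrow(m) < 3) {
    warning("fewer than 3 taxa in the union; correlation undefined")
    return(NA_real_)
  }
  cor(m[[paste0(use, "_a")]], m[[paste0(use, "_b")]], method = "spearman")
}

#' Extract reference sequences of identified taxa
#'
#' Collects all database sequences whose TaxID projects to one of the given
#' taxa at the given rank — the raw material for a focused reference
#' database. Options: an exclusion list (accessions or taxon names),
#' appended scrambled decoy proteins, and appended query peptides as extra
#' entries.
#'
#' @param db A `ref_db`.
#' @param tree A `tax_tree`.
#' @param taxa Character vector of taxon names (or integer taxids) at `rank`.
#' @param rank Ladder rank of `taxa` (default `"family"`).
#' @param exclude Optional accessions or taxon names to drop.
#' @param add_decoys Append a scrambled decoy for every extracted protein.
#' @param queries Optional query records (tibble with `query_id`, `peptide`)
#'   appended as entries.
#' @param path Optional FASTA output path.
#' @param seed Seed for decoy scrambling.
#' @return Tibble of the extracted entries (`accession`, `taxid`, `seq`);
#'   written to `path` when given.
#' @export
extract_taxon_sequences <- function(db, tree, taxa, rank = "family",
                                    exclude = NULL, add_decoys = FALSE,
                                    queries = NULL, path = NULL,
                                    seed = NULL) {
  stopifnot(rank %in% TAX_RANKS)
  if (length(taxa) == 0) stop("empty taxa set")
  lin <- tax_lineage(tree, db$taxid)
  keep <- lin[[rank]] %in% taxa | lin[[paste0(rank, "_taxid")]] %in% taxa
  keep[is.na(keep)] <- FALSE
  out <- tibble::as_tibble(db[keep, c("accession", "taxid", "seq")])
  if (!is.null(exclude)) {
    drop <- out$accession %in% exclude | lin[[rank]][keep] %in% exclude
    out <- out[!drop, , drop = FALSE]
  }
  if (nrow(out) == 0) warning("no sequences matched the requested taxa")
  if (add_decoys && nrow(out) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      accession = paste0(out$accession, "_DECOY"), taxid = NA_integer_,
      seq = make_decoy(out$seq, seed = seed)))
  }
  if (!is.null(queries)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      accession = queries$query_id, taxid = NA_integer_,
      seq = queries$peptide))
  }
  if (!is.null(path) && nrow(out) > 0) {
    fa <- out
    fa$desc <- ifelse(is.na(fa$taxid), "", paste0("OX=", fa$taxid))
    write_fasta(fa, path)
  }
  out
}

#' Complement a reference database with extracted sequences
#'
#' Concatenates a (typically metagenome-derived) database with sequences
#' extracted for de novo-identified taxa, removing exact duplicate sequences
#' (after L-normalization; first occurrence wins, so original entries take
#' precedence). Provenance is kept in a `source` column / FASTA header tag.
#'
#' @param base FASTA path or tibble (`accession`, `seq`): the database to
#'   complement.
#' @param extracted FASTA path or tibble: sequences of the identified taxa,
#'   e.g. from [extract_taxon_sequences()].
#' @param path Optional merged FASTA output path.
#' @return Tibble (`accession`, `seq`, `source`) of the merged entries.
#' @export
complement_db <- function(base, extracted, path = NULL) {
  load_entries <- function(x, src) {
    fa <- if (is.character(x)) read_fasta(x) else x
    tibble::tibble(accession = fa$accession, seq = normalize_il(fa$seq),
                   source = src,
                   taxid = if ("taxid" %in% names(fa)) fa$taxid else
                     NA_integer_)
  }
  merged <- dplyr::bind_rows(load_entries(base, "base"),
                             load_entries(extracted, "complement"))
  merged <- merged[!duplicated(merged$seq), , drop = FALSE]
  message("complement_db: ", sum(merged$source == "base"), " base + ",
          sum(merged$source == "complement"),
          " complement entries after deduplication")
  if (!is.null(path)) {
    fa <- merged
    fa$desc <- paste0("src=", fa$source,
                      ifelse(is.na(fa$taxid), "",
                             paste0(" OX=", fa$taxid)))
    write_fasta(fa, path)
  }
  merged
}
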