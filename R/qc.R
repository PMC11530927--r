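# Spectral-quality classification of aligned de novo peptides and
# evaluation of database-search coverage against de novo evidence.

QC_CATEGORIES <- c("exact", "exact_tag", "aligned", "aligned_tag",
                   "unmatched")

# Comparisons against 100 absorb tabular rounding.
QC_TOL <- 1e-6

#' Classify alignment quality of de novo queries
#'
#' Each query's best retained hit (maximal bitscore; ties by pident, qcov,
#' then subject accession) determines its category: `exact` (100% identity,
#' 100% coverage), `exact_tag` (100% identity, <100% coverage), `aligned`
#' (<100% identity, 100% coverage), `aligned_tag` (both <100%), and
#' `unmatched` for queries without a retained hit. The partition is
#' exhaustive and mutually exclusive.
#'
#' @param records De novo records tibble (targets; `query_id`, `score`).
#' @param hits Retained hits tibble (after [filter_hits()]).
#' @return Tibble `query_id`, `score`, `category`, plus the best hit's
#'   `pident`, `qcov`, `bitscore` (`NA` for unmatched).
#' @export
classify_alignment_quality <- function(records, hits) {
  best <- hits |>
    dplyr::arrange(dplyr::desc(.data$bitscore), dplyr::desc(.data$pident),
                   dplyr::desc(.data$qcov), .data$subject_id) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
  out <- dplyr::left_join(
    records[c("query_id", "score")],
    best[c("query_id", "pident", "qcov", "bitscore")], by = "query_id")
  id100 <- !is.na(out$pident) & out$pident >= 100 - QC_TOL
  cov100 <- !is.na(out$qcov) & out$qcov >= 100 - QC_TOL
  out$category <- dplyr::case_when(
    is.na(out$pident) ~ "unmatched",
    id100 & cov100 ~ "exact",
    id100 & !cov100 ~ "exact_tag",
    !id100 & cov100 ~ "aligned",
    .default = "aligned_tag")
  out$category <- factor(out$category, levels = QC_CATEGORIES)
  out
}

#' Match de novo records against a database-search PSM table
#'
#' Joins on the scan reference when both sides carry one, otherwise on the
#' normalized (modification-stripped, I->L) peptide string — cross-tool scan
#' numbering is unreliable, peptide strings are not.
#'
#' @param records De novo records tibble.
#' @param psm PSM table (data frame with a `Peptide` column, optionally
#'   `Scan`), or `NULL` for no database-search data.
#' @return `records` with a `db_status` column: `"matched"`,
#'   `"not_detected"`, or `"unknown"` when no PSM table is supplied.
#' @export
match_psms <- function(records, psm = NULL) {
  if (is.null(psm)) {
    records$db_status <- "unknown"
    return(records)
  }
  if (!"Peptide" %in% names(psm)) {
    stop("PSM table lacks the \"Peptide\" column")
  }
  psm_scan <- find_col(psm, c("Scan", "scan"))
  use_scan <- !is.na(psm_scan) && !is.null(records$scan_ref) &&
    !all(is.na(records$scan_ref))
  if (use_scan) {
    keys <- as.character(psm[[psm_scan]])
    records$db_status <- ifelse(records$scan_ref %in% keys, "matched",
                                "not_detected")
  } else {
    keys <- normalize_il(strip_modifications(as.character(psm$Peptide)))
    records$db_status <- ifelse(records$peptide %in% keys, "matched",
                                "not_detected")
  }
  records
}

#' Fraction of high-quality spectra matched in database searching
#'
#' Among records with a de novo score at or above `threshold` (ALC >= 90 by
#' default), the fraction whose spectrum was matched by the database search.
#' A low value flags an incomplete reference database.
#'
#' @param records Records carrying a `db_status` column ([match_psms()]).
#' @param threshold Minimum score (default 90).
#' @return Fraction in \[0, 1\], or `NA` (with a warning) when no record
#'   reaches the threshold.
#' @export
high_quality_matched_fraction <- function(records, threshold = 90) {
  hq <- records[!is.na(records$score) & records$score >= threshold, ,
                drop = FALSE]
  if (nrow(hq) == 0) {
    warning("no records with score >= ", threshold,
            "; fraction undefined")
    return(NA_real_)
  }
  mean(hq$db_status == "matched")
}

#' Map database-search peptides to taxa
#'
#' Resolves each PSM peptide to the taxids of its protein accessions through
#' the search database, and reduces multi-protein peptides by the
#' conventional LCA of their proteins' lineages.
#'
#' @param psm PSM table with `Peptide` and `Accession` columns (semicolon- or
#'   colon-separated accession lists tolerated).
#' @param db The `ref_db` the search was run against.
#' @param tree A `tax_tree`.
#' @return Tibble: normalized `peptide` plus the 14 lineage columns.
#' @export
map_psm_taxa <- function(psm, db, tree) {
  stopifnot(all(c("Peptide", "Accession") %in% names(psm)))
  tbl <- tibble::tibble(
    peptide = normalize_il(strip_modifications(as.character(psm$Peptide))),
    accession = strsplit(as.character(psm$Accession), "[;:]")
  ) |>
    tidyr::unnest("accession") |>
    dplyr::mutate(accession = trimws(.data$accession)) |>
    dplyr::left_join(tibble::as_tibble(db[c("accession", "taxid")]),
                     by = "accession") |>
    dplyr::filter(!is.na(.data$taxid)) |>
    dplyr::distinct(.data$peptide, .data$taxid)
  if (nrow(tbl) == 0) {
    warning("no PSM accessions matched the search database")
    return(dplyr::bind_cols(tibble::tibble(peptide = character()),
                            empty_lineage_row()[0, ]))
  }
  lin <- tax_lineage(tree, tbl$taxid)
  tbl <- dplyr::bind_cols(tbl["peptide"], lin[-1])
  tbl |>
    dplyr::group_by(.data$peptide) |>
    dplyr::group_modify(function(d, key) lca_conventional(d)) |>
    dplyr::ungroup()
}

#' Database coverage report: de novo vs database-search taxonomy
#'
#' Compares, at the requested ranks, the taxon distributions of four peptide
#' sets: peptides detected exclusively by de novo sequencing (`DN_only`),
#' all de novo peptides (`DN_all`), peptides detected exclusively by
#' database searching (`DB_only`), and all database-search peptides
#' (`DB_all`). Set membership is decided at the normalized peptide-string
#' level, so `DN_only = DN_all \\ DB_all`. Disagreement between the DN_all
#' and DB_all distributions signals database incompleteness (reported, not
#' judged).
#'
#' @param dn Tibble of de novo peptides with lineage columns: `peptide` plus
#'   rank name columns (e.g. [assign_lca()] joined to records).
#' @param db Tibble of database-search peptides with lineage columns (e.g.
#'   from [map_psm_taxa()]), or `NULL` — then only the DN sets are reported,
#'   with a warning.
#' @param ranks Ladder ranks to report (default order, family, genus).
#' @return A `coverage_report` tibble: `set`, `rank`, `taxon`, `n_peptides`,
#'   `fraction` (fractions sum to 1 within each set x rank over classified
#'   peptides).
#' @export
db_coverage_report <- function(dn, db = NULL,
                               ranks = c("order", "family", "genus")) {
  stopifnot(all(ranks %in% TAX_RANKS))
  dn <- dplyr::distinct(dn, .data$peptide, .keep_all = TRUE)
  sets <- list(DN_all = dn)
  if (is.null(db)) {
    warning("no database-search peptides supplied; ",
            "DN_only/DB sets omitted")
  } else {
    db <- dplyr::distinct(db, .data$peptide, .keep_all = TRUE)
    sets <- list(
      DN_only = dn[!dn$peptide %in% db$peptide, , drop = FALSE],
      DN_all = dn,
      DB_only = db[!db$peptide %in% dn$peptide, , drop = FALSE],
      DB_all = db)
  }
  out <- purrr::imap(sets, function(tbl, set) {
    purrr::map(ranks, function(r) {
      cls <- tbl[!is.na(tbl[[r]]), , drop = FALSE]
      if (nrow(cls) == 0) {
        return(tibble::tibble(set = set, rank = r, taxon = character(),
                              n_peptides = integer(), fraction = numeric()))
      }
      cls |>
        dplyr::count(taxon = .data[[r]], name = "n_peptides") |>
        dplyr::mutate(set = set, rank = r,
                      fraction = .data$n_peptides / sum(.data$n_peptides)) |>
        dplyr::select("set", "rank", "taxon", "n_peptides", "fraction")
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out$set <- factor(out$set, levels = c("DN_only", "DN_all", "DB_only",
                                        "DB_all"))
  structure(out, class = c("coverage_report", class(out)))
}
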