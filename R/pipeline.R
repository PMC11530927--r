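# End-to-end orchestration: prepare -> align -> LCA -> compose -> QC, with a
# resolved-config dump and a run manifest.

#' Pipeline configuration
#'
#' Bundles the per-stage parameter blocks with the engine choice and the run
#' seed. Every run writes its resolved configuration to the output directory.
#'
#' @param filter A [filter_config()].
#' @param align An [align_params()].
#' @param lca An [lca_params()].
#' @param rank Rank(s) for composition reporting (default family and genus).
#' @param freq_cut Minimum peptide count per reported taxon (default 5).
#' @param engine `"internal"` or `"diamond"`.
#' @param seed Integer run seed (drives decoy scrambling).
#' @return A `run_config` list.
#' @export
run_config <- function(filter = filter_config(), align = align_params(),
                       lca = lca_params(), rank = c("family", "genus"),
                       freq_cut = 5, engine = c("internal", "diamond"),
                       seed = 1L) {
  engine <- match.arg(engine)
  stopifnot(all(rank %in% TAX_RANKS))
  structure(list(filter = filter, align = align, lca = lca, rank = rank,
                 freq_cut = freq_cut, engine = engine,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full de novo profiling pipeline
#'
#' Stages: read and filter the de novo table, scramble decoys and write the
#' query FASTA, align targets+decoys against the reference database, filter
#' on bitscore, assign per-peptide consensus taxonomies, aggregate the
#' community composition per requested rank, and classify spectral quality
#' (plus database-search matching when a PSM table is supplied). All
#' artifacts and a manifest (versions, seed, per-stage counts) are written
#' to `out_dir`.
#'
#' @param denovo Path to a de novo table, or a records tibble from
#'   [read_denovo()].
#' @param db A `ref_db` (or FASTA path, passed to [build_reference_db()]).
#' @param taxonomy A `tax_tree` (or taxdump directory / lineage-table path).
#' @param out_dir Output directory (created).
#' @param config A [run_config()].
#' @param psm Optional PSM table (data frame or path) for spectral QC.
#' @return Invisibly, a list with `records`, `hits`, `lca`, `compositions`
#'   (one per rank), `qc`, and `manifest`.
#' @export
run_pipeline <- function(denovo, db, taxonomy, out_dir,
                         config = run_config(), psm = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  records <- stage("prepare", {
    r <- if (is.character(denovo)) read_denovo(denovo) else denovo
    r
  })
  n_parsed <- nrow(records)
  filtered <- stage("prepare", filter_denovo(records, config$filter))
  if (nrow(filtered) == 0) stop("no records pass the de novo filters")
  decoys <- stage("prepare", make_decoy_records(filtered,
                                                seed = config$seed))
  qfasta <- file.path(out_dir, "queries.fasta")
  write_query_fasta(filtered, decoys, qfasta)

  if (is.character(db)) db <- stage("align", build_reference_db(db))
  if (is.character(taxonomy)) taxonomy <- stage("lca",
                                                load_taxdump(taxonomy))
  hits <- stage("align", align_peptides(
    dplyr::bind_rows(filtered, decoys), db, config$align,
    engine = config$engine))
  write_hits(hits, file.path(out_dir, "hits.tsv"))
  retained <- filter_hits(hits, config$lca$min_bitscore)

  lca <- stage("lca", assign_lca(retained, taxonomy, config$lca))
  readr::write_tsv(lca, file.path(out_dir, paste0(
    "lca_", config$lca$method, ".tsv")), progress = FALSE)

  compositions <- lapply(setNames(config$rank, config$rank), function(r) {
    comp <- compose(lca, rank = r, freq_cut = config$freq_cut,
                    n_decoy_total = nrow(decoys))
    readr::write_tsv(tibble::as_tibble(comp),
                     file.path(out_dir, paste0("composition_", r, ".tsv")),
                     progress = FALSE)
    comp
  })

  qc <- stage("qc", {
    q <- classify_alignment_quality(filtered, retained)
    if (!is.null(psm) && is.character(psm)) psm <- read_denovo_table(psm)
    q2 <- match_psms(filtered, psm)
    q$db_status <- q2$db_status
    readr::write_tsv(q, file.path(out_dir, "spectral_qc.tsv"),
                     progress = FALSE)
    q
  })

  n_aligned_queries <- length(unique(hits$query_id[!hits$is_decoy_query]))
  n_classified <- sum(!lca$is_decoy_query)
  manifest <- list(
    package = as.character(utils::packageVersion("denovotax")),
    seed = config$seed, engine = config$engine,
    counts = list(parsed = n_parsed, filtered = nrow(filtered),
                  decoys = nrow(decoys),
                  aligned_queries = n_aligned_queries,
                  retained_hits = nrow(retained),
                  classified_queries = n_classified),
    lca_method = config$lca$method, ranks = config$rank,
    runtime_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      1)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(
    list(filter = unclass(config$filter),
         align = unclass(config$align), lca = unclass(config$lca),
         rank = config$rank, freq_cut = config$freq_cut,
         engine = config$engine, seed = config$seed),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, pretty = TRUE,
    null = "null")

  invisible(list(records = filtered, hits = hits, lca = lca,
                 compositions = compositions, qc = qc, manifest = manifest))
}
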