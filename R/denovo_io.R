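# Reading, filtering and normalizing de novo peptide tables, and writing the
# query FASTA (targets + scrambled decoys) used for alignment.

#' Strip modification annotations from a peptide string
#'
#' De novo tools write in-line modification masses such as `M(+15.99)` or
#' `N[Deamidation]`. Everything inside `(...)` or `[...]` spans is removed;
#' any other character passes through unchanged.
#'
#' @param raw Character vector of raw peptide strings.
#' @return Character vector of plain residue strings.
#' @export
#' @examples
#' strip_modifications("M(+15.99)PEPK")
strip_modifications <- function(raw) {
  out <- gsub("\\([^)]*\\)|\\[[^]]*\\]", "", raw)
  out <- gsub("[^A-Za-z]", "", out)
  if (any(!nzchar(out) & nzchar(raw))) {
    stop("modification stripping left an empty sequence for: ",
         paste(utils::head(raw[!nzchar(out)], 3), collapse = ", "))
  }
  toupper(out)
}

#' Replace isoleucine by leucine
#'
#' I and L are isobaric and indistinguishable by standard fragmentation
#' spectra, so both query peptides and reference sequences are folded onto L
#' before alignment.
#'
#' @param seq Character vector of residue strings.
#' @return Character vector with every `I` replaced by `L`.
#' @export
#' @examples
#' normalize_il("PEPTIDE")
normalize_il <- function(seq) {
  chartr("I", "L", toupper(seq))
}

#' Filter configuration for de novo peptide tables
#'
#' @param min_score_peaks Minimum ALC% for PEAKS-dialect records (default 70).
#' @param min_score_deepnovo Minimum score for DeepNovo-dialect records
#'   (default -0.1).
#' @param max_abs_ppm Optional maximum absolute precursor mass error (ppm).
#' @param min_length Optional minimum peptide length.
#' @param min_intensity Optional minimum peak intensity/area.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_score_peaks = 70, min_score_deepnovo = -0.1,
                          max_abs_ppm = NULL, min_length = NULL,
                          min_intensity = NULL) {
  stopifnot(min_score_peaks >= 0, min_score_peaks <= 100)
  structure(
    list(min_score_peaks = min_score_peaks,
         min_score_deepnovo = min_score_deepnovo,
         max_abs_ppm = max_abs_ppm, min_length = min_length,
         min_intensity = min_intensity),
    class = "filter_config"
  )
}

# Column lookup helper: first name in `candidates` present in `df`, or NA.
find_col <- function(df, candidates) {
  hit <- candidates[candidates %in% names(df)]
  if (length(hit) == 0) NA_character_ else hit[[1]]
}

read_denovo_table <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

detect_dialect <- function(df) {
  if (!is.na(find_col(df, c("ALC (%)", "ALC")))) return("peaks")
  if (!is.na(find_col(df, c("predicted_sequence", "predicted_score",
                            "output_score")))) return("deepnovo")
  "generic"
}

#' Read a de novo peptide table
#'
#' Understands the PEAKS de novo CSV export (columns `Peptide`, `ALC (%)`,
#' `ppm`, `Area`, `Scan`), DeepNovo-style TSVs (`predicted_sequence` with
#' comma-separated residues tolerated, `predicted_score`), and any delimited
#' table with a `Peptide` column. Peptides are normalized on read:
#' modification annotations stripped, then I replaced by L; the raw string is
#' preserved in `raw_peptide`.
#'
#' @param path Path to a delimited table (`.csv` is read as comma-separated,
#'   anything else as tab-separated).
#' @param dialect One of `"auto"`, `"peaks"`, `"deepnovo"`, `"generic"`.
#' @return Tibble with one row per usable input row and columns `query_id`,
#'   `peptide`, `raw_peptide`, `score`, `ppm_error`, `length`, `intensity`,
#'   `scan_ref`, `source_tool`, `is_decoy` (always `FALSE` on read).
#' @export
read_denovo <- function(path, dialect = c("auto", "peaks", "deepnovo",
                                          "generic")) {
  dialect <- match.arg(dialect)
  df <- read_denovo_table(path)
  if (dialect == "auto") dialect <- detect_dialect(df)

  pep_col <- switch(dialect,
    peaks = find_col(df, "Peptide"),
    deepnovo = find_col(df, c("predicted_sequence", "output_seq", "Peptide")),
    generic = find_col(df, "Peptide")
  )
  if (is.na(pep_col)) {
    stop("no peptide column found for dialect '", dialect,
         "': expected a column named \"Peptide\"",
         if (dialect == "deepnovo") " or \"predicted_sequence\"")
  }
  score_col <- switch(dialect,
    peaks = find_col(df, c("ALC (%)", "ALC")),
    deepnovo = find_col(df, c("predicted_score", "output_score", "Score")),
    generic = find_col(df, c("Score", "score", "ALC (%)", "ALC"))
  )

  raw <- as.character(df[[pep_col]])
  # DeepNovo writes residues comma-separated ("P,E,P"); tolerate anywhere.
  raw_clean <- gsub(",", "", raw)
  usable <- !is.na(raw) & nzchar(trimws(raw_clean))
  n_skipped <- sum(!usable)
  if (n_skipped > 0) {
    message("read_denovo: skipped ", n_skipped, " unreadable row(s)")
  }
  df <- df[usable, , drop = FALSE]
  raw <- raw[usable]
  raw_clean <- raw_clean[usable]

  scan_col <- find_col(df, c("Scan", "scan", "scan_ref"))
  ppm_col <- find_col(df, c("ppm", "PPM", "ppm_error"))
  area_col <- find_col(df, c("Area", "area", "Intensity", "intensity"))

  scan <- if (!is.na(scan_col)) as.character(df[[scan_col]]) else
    rep(NA_character_, nrow(df))
  qid <- if (!is.na(scan_col) && !anyNA(scan) && !anyDuplicated(scan)) {
    paste0("scan", gsub("[^A-Za-z0-9_.-]", "_", scan))
  } else {
    paste0("row", seq_len(nrow(df)) - 1L)
  }

  tibble::tibble(
    query_id = qid,
    peptide = normalize_il(strip_modifications(raw_clean)),
    raw_peptide = raw,
    score = if (!is.na(score_col)) as.numeric(df[[score_col]]) else NA_real_,
    ppm_error = if (!is.na(ppm_col)) as.numeric(df[[ppm_col]]) else NA_real_,
    intensity = if (!is.na(area_col)) as.numeric(df[[area_col]]) else NA_real_,
    scan_ref = scan,
    source_tool = dialect,
    is_decoy = FALSE
  ) |>
    dplyr::mutate(length = nchar(.data$peptide), .after = "ppm_error")
}

#' Filter de novo records on quality thresholds
#'
#' Applies the tool-appropriate minimum score (ALC% for PEAKS, raw score for
#' DeepNovo; generic tables use the PEAKS threshold when a score is present)
#' plus any optional ppm / length / intensity thresholds configured in `cfg`.
#' Records with a missing value for an optional threshold are kept; the ppm
#' filter applies to the absolute mass error.
#'
#' @param records Tibble from [read_denovo()].
#' @param cfg A [filter_config()].
#' @return The retained rows, same columns.
#' @export
filter_denovo <- function(records, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (nrow(records) == 0) return(records)
  min_score <- ifelse(records$source_tool == "deepnovo",
                      cfg$min_score_deepnovo, cfg$min_score_peaks)
  keep <- is.na(records$score) & records$source_tool == "generic" |
    (!is.na(records$score) & records$score >= min_score)
  if (!is.null(cfg$max_abs_ppm)) {
    keep <- keep & (is.na(records$ppm_error) |
                      abs(records$ppm_error) <= cfg$max_abs_ppm)
  }
  if (!is.null(cfg$min_length)) {
    keep <- keep & records$length >= cfg$min_length
  }
  if (!is.null(cfg$min_intensity)) {
    keep <- keep & (is.na(records$intensity) |
                      records$intensity >= cfg$min_intensity)
  }
  out <- records[keep, , drop = FALSE]
  message("filter_denovo: retained ", nrow(out), " of ", nrow(records),
          " records")
  out
}

#' Scramble peptides into decoy sequences
#'
#' Residues in front of the C-terminal tryptic cleavage site (R or K) are
#' uniformly permuted while the terminal residue stays fixed, so decoys keep
#' the composition, length, and cleavage signature of their targets. Peptides
#' not ending in K/R are permuted over their full length. Length-1 peptides
#' are returned unchanged with a warning.
#'
#' @param peptides Character vector of (normalized) peptide sequences.
#' @param seed Optional integer seed for reproducible scrambling.
#' @return Character vector of decoy sequences, same length and per-sequence
#'   residue multiset as the input.
#' @export
#' @examples
#' make_decoy("PEPTLDEK", seed = 1)
make_decoy <- function(peptides, seed = NULL) {
  if (any(nchar(peptides) < 2)) {
    warning("peptides shorter than 2 residues returned unchanged")
  }
  with_seed_if(seed, {
    vapply(peptides, function(p) {
      n <- nchar(p)
      if (n < 2) return(p)
      x <- strsplit(p, "", fixed = TRUE)[[1]]
      scramble_to <- if (x[n] %in% c("K", "R")) n - 1L else n
      x[seq_len(scramble_to)] <- sample(x[seq_len(scramble_to)])
      paste(x, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Build decoy records for a set of target records
#'
#' One decoy per target; `query_id` gets the suffix `_DECOY` and `is_decoy`
#' is set.
#'
#' @param records Tibble of target records.
#' @param seed Optional integer seed.
#' @return Tibble of decoy records, `nrow(records)` rows.
#' @export
make_decoy_records <- function(records, seed = NULL) {
  records |>
    dplyr::mutate(
      peptide = make_decoy(.data$peptide, seed = seed),
      query_id = paste0(.data$query_id, "_DECOY"),
      is_decoy = TRUE
    )
}

#' Write query FASTA of targets and decoys
#'
#' Headers are the `query_id` values; decoy entries are recognizable (and
#' recoverable on parse) by their `_DECOY` suffix.
#'
#' @param records Target records (tibble with `query_id`, `peptide`).
#' @param decoys Decoy records, e.g. from [make_decoy_records()]; may be
#'   `NULL` to write targets only.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_query_fasta <- function(records, decoys = NULL, path) {
  if (nrow(records) == 0) stop("no records to write")
  all <- dplyr::bind_rows(records, decoys)
  stopifnot(!anyDuplicated(all$query_id))
  write_fasta(setNames(all$peptide, all$query_id), path)
}

#' Read a query FASTA back into records
#'
#' Inverse of [write_query_fasta()]: recovers `query_id`, `peptide` and the
#' decoy flag from the `_DECOY` header suffix.
#'
#' @param path FASTA path.
#' @return Tibble with `query_id`, `peptide`, `is_decoy`.
#' @export
read_query_fasta <- function(path) {
  fa <- read_fasta(path)
  tibble::tibble(
    query_id = fa$accession,
    peptide = fa$seq,
    is_decoy = grepl("_DECOY$", fa$accession)
  )
}
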