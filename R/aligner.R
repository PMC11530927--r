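# Short-peptide homology search: reference database handling, the external
# DIAMOND invocation, an internal Biostrings-based local aligner usable at
# fixture scale, and blast-tabular hit parsing/filtering.

#' Alignment parameter set
#'
#' Defaults follow parameter choices established for de novo peptides with
#' sequencing errors: PAM70, gap opening 2 / extension 4, minimum percent
#' identity 85, minimum query coverage 80 (best range 75-85), contiguous-seed
#' mode for short queries.
#'
#' @param matrix Substitution matrix: `"PAM70"`, `"PAM30"` or `"BLOSUM62"`.
#' @param gap_open,gap_extend Positive gap penalties (a gap of length g costs
#'   `gap_open + g * gap_extend`).
#' @param min_pident Minimum percent identity reported (default 85).
#' @param min_qcov Minimum percent query coverage reported (default 80).
#' @param seed_mode Seed search mode for the external aligner: `"default"`,
#'   `"query_indexed"` or `"ctg"` (contiguous seeds, default). The internal
#'   engine uses `seed_len` contiguous seeds for its candidate prefilter.
#' @param custom_seed_shapes Optional seed shape specs passed through to the
#'   external aligner (`--shape-mask`-style strings); no default.
#' @param max_hits_per_query Maximum retained alignments per query (default 25).
#' @param seed_len Contiguous seed length of the internal engine's candidate
#'   prefilter (default 4).
#' @return An `align_params` list.
#' @export
align_params <- function(matrix = c("PAM70", "PAM30", "BLOSUM62"),
                         gap_open = 2, gap_extend = 4, min_pident = 85,
                         min_qcov = 80,
                         seed_mode = c("ctg", "query_indexed", "default"),
                         custom_seed_shapes = NULL, max_hits_per_query = 25,
                         seed_len = 4) {
  matrix <- match.arg(matrix)
  seed_mode <- match.arg(seed_mode)
  stopifnot(gap_open > 0, gap_extend > 0,
            min_pident >= 0, min_pident <= 100,  # 0 disables the filter
            min_qcov >= 0, min_qcov <= 100,
            max_hits_per_query >= 1, seed_len >= 1)
  structure(
    list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
         min_pident = min_pident, min_qcov = min_qcov, seed_mode = seed_mode,
         custom_seed_shapes = custom_seed_shapes,
         max_hits_per_query = max_hits_per_query, seed_len = seed_len),
    class = "align_params"
  )
}

taxid_from_headers <- function(desc, taxid_regex = NULL) {
  patterns <- c("OX=([0-9]+)", "TaxID=([0-9]+)")
  if (!is.null(taxid_regex)) patterns <- c(taxid_regex, patterns)
  out <- rep(NA_integer_, length(desc))
  for (p in patterns) {
    miss <- is.na(out)
    if (!any(miss)) break
    m <- regmatches(desc[miss], regexec(p, desc[miss]))
    val <- vapply(m, function(x) if (length(x) >= 2) x[[2]] else
      NA_character_, character(1))
    out[miss] <- suppressWarnings(as.integer(val))
  }
  out
}

#' Build a protein reference database with TaxIDs
#'
#' Reads a protein FASTA, L-normalizes sequences, and derives an NCBI TaxID
#' per entry from the headers (UniProtKB `OX=` token, UniRef `TaxID=` token,
#' or a custom regex) or from a two-column accession-to-taxid map file.
#'
#' @param fasta Path to a protein FASTA, or a tibble with columns
#'   `accession`, `taxid`, `seq` (already built, e.g. synthetic).
#' @param taxid_map Optional path to a headerless two-column TSV
#'   (accession, taxid) or an equivalent data frame.
#' @param taxid_regex Optional regex with one capture group for the taxid.
#' @return A `ref_db` tibble with columns `accession`, `taxid`, `seq`.
#' @export
build_reference_db <- function(fasta, taxid_map = NULL, taxid_regex = NULL) {
  if (is.data.frame(fasta)) {
    stopifnot(all(c("accession", "taxid", "seq") %in% names(fasta)))
    db <- tibble::as_tibble(fasta[c("accession", "taxid", "seq")])
    db$seq <- normalize_il(db$seq)
    return(structure(db, class = c("ref_db", class(db))))
  }
  fa <- read_fasta(fasta)
  taxid <- taxid_from_headers(fa$desc, taxid_regex)
  # fall back to the full header line (some dialects put OX= in the accession)
  miss <- is.na(taxid)
  taxid[miss] <- taxid_from_headers(fa$accession[miss], taxid_regex)
  if (!is.null(taxid_map)) {
    map <- if (is.data.frame(taxid_map)) taxid_map else
      readr::read_tsv(taxid_map, col_names = c("accession", "taxid"),
                      show_col_types = FALSE, progress = FALSE)
    idx <- match(fa$accession, map$accession)
    miss <- is.na(taxid)
    taxid[miss] <- as.integer(map$taxid[idx[miss]])
  }
  if (mean(is.na(taxid)) > 0.5) {
    stop("could not derive TaxIDs for >50% of entries ",
         "(tried OX=, TaxID=", if (!is.null(taxid_regex)) ", custom regex",
         if (!is.null(taxid_map)) ", map file",
         "); supply taxid_map or taxid_regex")
  }
  n_drop <- sum(is.na(taxid))
  if (n_drop > 0) {
    message("build_reference_db: dropped ", n_drop, " entries without TaxID")
  }
  db <- tibble::tibble(accession = fa$accession, taxid = taxid,
                       seq = normalize_il(fa$seq))[!is.na(taxid), ]
  structure(db, class = c("ref_db", class(db)))
}

#' Compose the external DIAMOND blastp command
#'
#' Builds the argument vector for a short-peptide-optimized DIAMOND blastp
#' run: the configured matrix and gap penalties, identity and query-cover
#' cutoffs, the seed-search mode, with low-complexity masking and
#' composition-based statistics disabled (both silently drop short-peptide
#' hits), and a tabular output format carrying query, subject, identity,
#' coverage, bitscore, E-value and subject taxids.
#'
#' @param query_fasta Query FASTA path.
#' @param db Path to a DIAMOND database (`.dmnd`).
#' @param out Output path for the tabular hits.
#' @param params An [align_params()].
#' @param threads Number of threads.
#' @return Character vector of command-line arguments (first element is the
#'   subcommand).
#' @export
diamond_command <- function(query_fasta, db, out, params = align_params(),
                            threads = 1) {
  args <- c(
    "blastp", "--query", query_fasta, "--db", db, "--out", out,
    "--matrix", params$matrix,
    "--gapopen", params$gap_open, "--gapextend", params$gap_extend,
    "--id", params$min_pident, "--query-cover", params$min_qcov,
    "--masking", "0", "--comp-based-stats", "0",
    "--max-target-seqs", params$max_hits_per_query,
    "--threads", threads,
    "--outfmt", "6", "qseqid", "sseqid", "pident", "length", "mismatch",
    "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore",
    "qcovhsp", "staxids"
  )
  if (params$seed_mode == "ctg") args <- c(args, "--algo", "ctg")
  if (params$seed_mode == "query_indexed") args <- c(args, "--algo", "1")
  if (!is.null(params$custom_seed_shapes)) {
    args <- c(args, "--shape-mask",
              paste(params$custom_seed_shapes, collapse = ","))
  }
  as.character(args)
}

#' Run DIAMOND on a query FASTA
#'
#' Thin invoker around [diamond_command()]. Requires the `diamond` binary on
#' the PATH; when it is absent an actionable error points at the internal
#' engine (`align_peptides(engine = "internal")`).
#'
#' @inheritParams diamond_command
#' @param dry_run If `TRUE`, return the argument vector without invoking
#'   anything (no binary required).
#' @return Path to the tabular output (or the argument vector for dry runs).
#' @export
run_diamond <- function(query_fasta, db, out, params = align_params(),
                        threads = 1, dry_run = FALSE) {
  if (!dry_run && (!file.exists(query_fasta) ||
                     length(Biostrings::fasta.index(query_fasta)$recno) == 0)) {
    stop("query FASTA is missing or empty: ", query_fasta)
  }
  args <- diamond_command(query_fasta, db, out, params, threads)
  if (dry_run) return(args)
  bin <- Sys.which("diamond")
  if (!nzchar(bin)) {
    stop("the 'diamond' binary is not on the PATH; either install DIAMOND ",
         "or use the internal engine: align_peptides(..., engine = ",
         "\"internal\")")
  }
  status <- system2(bin, args, stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0) {
    stop("diamond exited with status ", code, ":\n",
         paste(utils::tail(status, 20), collapse = "\n"))
  }
  out
}

# Candidate query-subject pairs sharing at least one exact k-mer.
seed_candidates <- function(qpeps, sseqs, k) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  db_idx <- tibble::tibble(sidx = seq_along(sseqs),
                           kmer = lapply(sseqs, kmers)) |>
    tidyr::unnest("kmer")
  q_idx <- tibble::tibble(qidx = seq_along(qpeps),
                          kmer = lapply(qpeps, kmers)) |>
    tidyr::unnest("kmer")
  short <- which(nchar(qpeps) < k)
  pairs <- dplyr::distinct(
    dplyr::inner_join(q_idx, db_idx, by = "kmer",
                      relationship = "many-to-many")[c("qidx", "sidx")])
  if (length(short) > 0) {  # queries shorter than the seed: scan everything
    pairs <- dplyr::bind_rows(
      pairs, tidyr::expand_grid(qidx = short, sidx = seq_along(sseqs)))
  }
  pairs
}

#' Align query peptides against a reference database
#'
#' The internal engine computes exact local affine-gap alignments with
#' `Biostrings::pairwiseAlignment` under the configured matrix and penalties.
#' Candidate subjects are prefiltered by shared exact `seed_len`-mers
#' (`exhaustive = TRUE` disables the prefilter and scans every subject).
#' Reported per hit: percent identity over alignment columns, percent query
#' coverage, the raw score, an approximate bitscore from ungapped
#' Karlin-Altschul statistics, and an approximate E-value. Hits below
#' `min_pident`/`min_qcov` are not reported; at most `max_hits_per_query`
#' hits are kept per query (by bitscore, ties by pident, qcov, subject).
#'
#' @param queries Tibble with `query_id`, `peptide` (and optional `is_decoy`),
#'   or a query FASTA path as written by [write_query_fasta()].
#' @param db A `ref_db` from [build_reference_db()].
#' @param params An [align_params()].
#' @param engine `"internal"` or `"diamond"`.
#' @param exhaustive Internal engine only: align every query against every
#'   subject (test-scale oracle mode).
#' @return A hits tibble: `query_id`, `subject_id`, `pident`, `qcov`,
#'   `raw_score`, `bitscore`, `evalue`, `subject_taxids` (list column),
#'   `is_decoy_query`.
#' @export
align_peptides <- function(queries, db, params = align_params(),
                           engine = c("internal", "diamond"),
                           exhaustive = FALSE) {
  engine <- match.arg(engine)
  if (is.character(queries)) queries <- read_query_fasta(queries)
  if (!"is_decoy" %in% names(queries)) {
    queries$is_decoy <- grepl("_DECOY$", queries$query_id)
  }
  if (nrow(queries) == 0) stop("no query peptides supplied")
  if (engine == "diamond") {
    qf <- tempfile(fileext = ".fasta")
    on.exit(unlink(qf))
    write_query_fasta(queries, NULL, qf)
    out <- tempfile(fileext = ".tsv")
    run_diamond(qf, db, out, params)
    return(parse_hits(out, taxid_map = db))
  }
  align_internal(queries, db, params, exhaustive)
}

align_internal <- function(queries, db, params, exhaustive = FALSE) {
  qpeps <- queries$peptide
  if (any(!nzchar(qpeps))) stop("empty query peptide")
  pairs <- if (exhaustive) {
    tidyr::expand_grid(qidx = seq_len(nrow(queries)),
                       sidx = seq_len(nrow(db)))
  } else {
    seed_candidates(qpeps, db$seq, params$seed_len)
  }
  if (nrow(pairs) == 0) return(empty_hits())
  mat <- get_substitution_matrix(params$matrix)
  kp <- karlin_for_matrix(params$matrix)
  db_residues <- sum(nchar(db$seq))

  res <- pairs |>
    dplyr::group_by(.data$sidx) |>
    dplyr::group_map(function(grp, key) {
      sidx <- key$sidx[[1]]
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(qpeps[grp$qidx]),
        Biostrings::AAString(db$seq[sidx]),
        type = "local", substitutionMatrix = mat,
        gapOpening = params$gap_open, gapExtension = params$gap_extend)
      raw <- Biostrings::score(aln)
      ok <- raw > 0
      if (!any(ok)) return(NULL)
      ncols <- Biostrings::nchar(aln)[ok]
      nmatch <- Biostrings::nmatch(aln)[ok]
      pat <- Biostrings::pattern(aln)
      qspan <- (BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1L)[ok]
      qlen <- nchar(qpeps[grp$qidx])[ok]
      tibble::tibble(
        qidx = grp$qidx[ok], sidx = sidx,
        pident = 100 * nmatch / ncols,
        qcov = 100 * qspan / qlen,
        raw_score = raw[ok])
    }) |>
    dplyr::bind_rows()
  if (nrow(res) == 0) return(empty_hits())

  res <- res |>
    dplyr::filter(.data$pident >= params$min_pident,
                  .data$qcov >= params$min_qcov) |>
    dplyr::mutate(
      bitscore = bitscore_from_raw(.data$raw_score, params$matrix),
      evalue = kp$K * nchar(qpeps)[.data$qidx] * db_residues *
        exp(-kp$lambda * .data$raw_score),
      query_id = queries$query_id[.data$qidx],
      subject_id = db$accession[.data$sidx],
      is_decoy_query = queries$is_decoy[.data$qidx],
      subject_taxids = as.list(db$taxid[.data$sidx])
    ) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::arrange(dplyr::desc(.data$bitscore), dplyr::desc(.data$pident),
                   dplyr::desc(.data$qcov), .data$subject_id,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = params$max_hits_per_query) |>
    dplyr::ungroup()
  res[c("query_id", "subject_id", "pident", "qcov", "raw_score", "bitscore",
        "evalue", "subject_taxids", "is_decoy_query")]
}

empty_hits <- function() {
  tibble::tibble(query_id = character(), subject_id = character(),
                 pident = numeric(), qcov = numeric(), raw_score = numeric(),
                 bitscore = numeric(), evalue = numeric(),
                 subject_taxids = list(), is_decoy_query = logical())
}

#' Write hits in blast tabular (outfmt-6) dialect
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore qcovhsp staxids. Alignment coordinates that the
#' internal engine does not track are written as 0.
#'
#' @param hits Hits tibble from [align_peptides()] or [parse_hits()].
#' @param path Output TSV path (no header, per the dialect).
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  out <- tibble::tibble(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = round(hits$pident, 3), length = 0L, mismatch = 0L,
    gapopen = 0L, qstart = 0L, qend = 0L, sstart = 0L, send = 0L,
    evalue = signif(hits$evalue, 3), bitscore = round(hits$bitscore, 1),
    qcovhsp = round(hits$qcov, 3),
    staxids = vapply(hits$subject_taxids, paste, character(1),
                     collapse = ";")
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Parse blast tabular alignment output
#'
#' Accepts the 12-column blast outfmt-6 dialect or the extended form with
#' `qcovhsp` and `staxids` columns appended (as requested from the external
#' aligner). Decoy queries are recognized by the `_DECOY` header suffix;
#' multi-taxid cells (`"562;623"`) are split. When the taxids column is
#' absent, subject taxids are resolved through `taxid_map`.
#'
#' @param tabular Path to the tabular file.
#' @param taxid_map Optional accession-to-taxid mapping (a `ref_db` or any
#'   data frame with `accession`, `taxid`).
#' @return Hits tibble as in [align_peptides()] (`raw_score` is `NA`:
#'   external aligners report bitscores only).
#' @export
parse_hits <- function(tabular, taxid_map = NULL) {
  raw <- readr::read_tsv(tabular, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (nrow(raw) == 0) return(empty_hits())
  if (ncol(raw) < 12) stop("expected >= 12 blast tabular columns, got ",
                           ncol(raw))
  num <- function(x) suppressWarnings(as.numeric(x))
  pident <- num(raw[[3]])
  evalue <- num(raw[[11]])
  bitscore <- num(raw[[12]])
  qcov <- if (ncol(raw) >= 13) num(raw[[13]]) else rep(NA_real_, nrow(raw))
  staxids <- if (ncol(raw) >= 14) raw[[14]] else rep(NA_character_, nrow(raw))
  bad <- is.na(pident) | is.na(bitscore)
  if (any(bad)) message("parse_hits: skipped ", sum(bad), " malformed row(s)")
  taxids <- lapply(strsplit(staxids, ";", fixed = TRUE), function(x)
    suppressWarnings(as.integer(x[!is.na(x) & nzchar(x)])))
  if (!is.null(taxid_map)) {
    idx <- match(raw[[2]], taxid_map$accession)
    fill <- lengths(taxids) == 0 & !is.na(idx)
    taxids[fill] <- as.list(as.integer(taxid_map$taxid[idx[fill]]))
  }
  tibble::tibble(
    query_id = raw[[1]], subject_id = raw[[2]], pident = pident,
    qcov = qcov, raw_score = NA_real_, bitscore = bitscore, evalue = evalue,
    subject_taxids = taxids,
    is_decoy_query = grepl("_DECOY$", raw[[1]])
  )[!bad, ]
}

#' Filter hits on a minimum bitscore
#'
#' The threshold is inclusive: a hit at exactly `min_bitscore` is retained.
#'
#' @param hits Hits tibble.
#' @param min_bitscore Minimum bitscore (default 25).
#' @return The retained hits.
#' @export
filter_hits <- function(hits, min_bitscore = 25) {
  hits[hits$bitscore >= min_bitscore, , drop = FALSE]
}
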