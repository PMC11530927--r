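# Small shared helpers: FASTA I/O and seeded evaluation.

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector (names become headers) or a tibble with
#'   columns `accession` and `seq` (plus optional `desc` appended to headers).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) {
    headers <- seqs$accession
    if (!is.null(seqs$desc)) headers <- paste(headers, seqs$desc)
    seqs <- setNames(seqs$seq, headers)
  }
  if (length(seqs) == 0) stop("no sequences to write")
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file into a tibble
#'
#' @param path FASTA file path.
#' @return Tibble with columns `accession` (first header token), `desc`
#'   (remainder of the header) and `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  hdr <- names(x)
  tibble::tibble(
    accession = sub("\\s.*$", "", hdr),
    desc = ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), ""),
    seq = unname(as.character(x))
  )
}

# Evaluate `expr` under a fixed RNG seed when `seed` is non-NULL, leaving the
# caller's RNG state untouched.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive a deterministic child seed from a base seed, kept within 32-bit range.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
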