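# Simulation of de novo sequencing errors: equal-mass (isobaric)
# substitutions, fragment inversions, and codon-level mutations, plus the
# combined dataset that mixes the error types at their observed rates.

ERROR_TYPES <- c("sub_1_12", "sub_2_2", "sub_3_3", "sub_2_3", "sub_4_4",
                 "sub_5_5", "sub_6_6", "inversion", "other")

# Per-type occurrence rates of de novo sequencing errors in common tools
# (1-by-1-or-2, 2-by-2, 3-by-3, 2-by-3, 4-by-4, 5-by-5, 6-by-6 equal-mass
# substitutions; 2-or-3-residue inversions; codon-level "other" mutations).
COMBINED_ERROR_RATES <- c(
  sub_1_12 = 0.063, sub_2_2 = 0.137, sub_3_3 = 0.063, sub_2_3 = 0.037,
  sub_4_4 = 0.097, sub_5_5 = 0.076, sub_6_6 = 0.068,
  inversion = 0.161, other = 0.297
)

#' Error-simulator configuration
#'
#' @param substitution_prob Per-window substitution chance for equal-mass
#'   substitutions (default 0.25).
#' @param inversion_prob Per-fragment randomization chance for inversions
#'   (default 0.05).
#' @param mutation_prob Per-nucleotide substitution chance for codon-level
#'   mutations (default 0.01).
#' @param max_combo_len Longest residue combination considered isobaric
#'   (default 6).
#' @param mass_tolerance Mass window (Da) within which residue combinations
#'   count as equal-mass (default 1e-4).
#' @param combined_rates Named per-error-type occurrence probabilities for the
#'   combined dataset; must cover the nine error types and sum to 1 within
#'   0.005.
#' @param seed Integer RNG seed.
#' @return An `error_sim_config` list.
#' @export
error_sim_config <- function(substitution_prob = 0.25, inversion_prob = 0.05,
                             mutation_prob = 0.01, max_combo_len = 6,
                             mass_tolerance = 1e-4,
                             combined_rates = COMBINED_ERROR_RATES,
                             seed = NULL) {
  probs <- c(substitution_prob, inversion_prob, mutation_prob, combined_rates)
  stopifnot(all(probs >= 0 & probs <= 1), max_combo_len >= 1,
            mass_tolerance > 0,
            setequal(names(combined_rates), ERROR_TYPES),
            abs(sum(combined_rates) - 1) <= 0.005)
  structure(
    list(substitution_prob = substitution_prob,
         inversion_prob = inversion_prob, mutation_prob = mutation_prob,
         max_combo_len = max_combo_len, mass_tolerance = mass_tolerance,
         combined_rates = combined_rates[ERROR_TYPES], seed = seed),
    class = "error_sim_config"
  )
}

# Enumerate all residue multisets of size k over the 19-letter alphabet as
# sorted index matrices (stars-and-bars over combn), k x C(19+k-1, k).
multiset_index_matrix <- function(k, n_letters = length(ALPHABET19)) {
  cmb <- utils::combn(n_letters + k - 1L, k)
  cmb - (seq_len(k) - 1L)
}

#' Build the isobaric substitution table
#'
#' Enumerates every residue multiset of length 1..`max_combo_len` over the
#' 19-letter (I-free) alphabet, computes its monoisotopic mass, and groups
#' multisets into equal-mass classes by quantizing mass at `mass_tolerance`.
#' Orderings of a multiset are counted analytically (`n_orderings`) rather
#' than enumerated, so the table stays small.
#'
#' @param max_combo_len Longest combination length (default 6).
#' @param mass_tolerance Quantization width in Da (default 1e-4).
#' @return An `isobaric_table` object.
#' @export
build_isobaric_table <- function(max_combo_len = 6, mass_tolerance = 1e-4) {
  if (max_combo_len < 1) stop("max_combo_len must be >= 1")
  masses_abc <- AA_MASSES[ALPHABET19]  # alphabetical order, matching idx
  parts <- lapply(seq_len(max_combo_len), function(k) {
    idx <- multiset_index_matrix(k)
    mass <- colSums(matrix(masses_abc[idx], nrow = k))
    # multinomial count of distinct orderings: k! / prod(count!)
    nperm <- apply(idx, 2, function(col) {
      exp(lfactorial(k) - sum(lfactorial(tabulate(col, length(ALPHABET19)))))
    })
    ms <- apply(matrix(ALPHABET19[idx], nrow = k), 2, paste, collapse = "")
    tibble::tibble(ms = ms, len = k, mass = mass,
                   key = round(mass / mass_tolerance),
                   n_orderings = round(nperm))
  })
  tbl <- dplyr::arrange(dplyr::bind_rows(parts), .data$key, .data$len,
                        .data$ms)
  ukeys <- unique(tbl$key)
  first <- match(ukeys, tbl$key)
  structure(
    list(tbl = tbl, ukeys = ukeys,
         row_start = first, row_end = c(first[-1] - 1L, nrow(tbl)),
         max_combo_len = max_combo_len, mass_tolerance = mass_tolerance),
    class = "isobaric_table"
  )
}

#' @export
print.isobaric_table <- function(x, ...) {
  cat("Isobaric substitution table: combinations up to length",
      x$max_combo_len, "at", format(x$mass_tolerance), "Da\n",
      nrow(x$tbl), "multisets in", length(x$ukeys), "mass classes\n")
  invisible(x)
}

# All multisets in the same mass class as window string `w`.
iso_class_members <- function(table, w) {
  key <- round(sum(AA_MASSES[strsplit(w, "", fixed = TRUE)[[1]]]) /
                 table$mass_tolerance)
  i <- findInterval(key, table$ukeys)
  if (i == 0 || table$ukeys[i] != key) return(NULL)
  table$tbl[table$row_start[i]:table$row_end[i], , drop = FALSE]
}

sorted_string <- function(w) {
  paste(sort(strsplit(w, "", fixed = TRUE)[[1]]), collapse = "")
}

# Number of alternative strings of the target lengths for window `w`, and the
# candidate multisets. The window's own string is excluded; other orderings of
# its own multiset count as alternatives.
iso_alternatives <- function(table, w, target_lens) {
  members <- iso_class_members(table, w)
  if (is.null(members)) return(NULL)
  cand <- members[members$len %in% target_lens, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  own <- sorted_string(w)
  weight <- cand$n_orderings - (cand$ms == own & cand$len == nchar(w))
  cand <- cand[weight > 0, , drop = FALSE]
  weight <- weight[weight > 0]
  if (nrow(cand) == 0) return(NULL)
  list(cand = cand, weight = weight, own = own)
}

# Draw one replacement string uniformly among the alternative strings.
sample_replacement <- function(alts, w) {
  i <- if (length(alts$weight) == 1) 1L else
    sample.int(length(alts$weight), 1, prob = alts$weight)
  letters_ms <- strsplit(alts$cand$ms[i], "", fixed = TRUE)[[1]]
  repeat {
    out <- paste(if (length(letters_ms) == 1) letters_ms else
      sample(letters_ms), collapse = "")
    if (out != w) return(out)
  }
}

# Window specs (source length -> target lengths) for a named length pair.
length_pair_specs <- function(length_pair, max_combo_len = 6) {
  switch(length_pair,
    "1:1/2" = list(list(a = 1L, bs = c(1L, 2L)), list(a = 2L, bs = 1L)),
    "2:2" = list(list(a = 2L, bs = 2L)),
    "2:3" = list(list(a = 2L, bs = 3L), list(a = 3L, bs = 2L)),
    "3:3" = list(list(a = 3L, bs = 3L)),
    "4:4" = list(list(a = 4L, bs = 4L)),
    "5:5" = list(list(a = 5L, bs = 5L)),
    "6:6" = list(list(a = 6L, bs = 6L)),
    "any" = lapply(seq_len(max_combo_len), function(a)
      list(a = a, bs = seq_len(max_combo_len))),
    stop("unknown length pair: ", length_pair)
  )
}

# Map a length pair to its canonical error-type label.
length_pair_type <- function(length_pair) {
  switch(length_pair,
    "1:1/2" = "sub_1_12", "2:2" = "sub_2_2", "2:3" = "sub_2_3",
    "3:3" = "sub_3_3", "4:4" = "sub_4_4", "5:5" = "sub_5_5",
    "6:6" = "sub_6_6", "any" = "sub_any")
}

errored_tibble <- function(original, altered, error_type, applicable) {
  tibble::tibble(
    original = original, altered = altered, error_type = error_type,
    applicable = applicable, changed = altered != original,
    levenshtein = levenshtein(original, altered)
  )
}

#' Apply equal-mass substitutions to peptides
#'
#' A sliding window of the source length scans each peptide left to right;
#' every window whose residue string has an equal-mass alternative of the
#' target length is substituted with probability `prob` by a replacement drawn
#' uniformly among all alternative strings of its mass class. After a
#' substitution the scan resumes after the replaced span, so edits never
#' overlap. Monoisotopic mass is conserved within the table's tolerance.
#'
#' @param seqs Character vector of L-normalized peptides.
#' @param length_pair One of `"1:1/2"`, `"2:2"`, `"2:3"`, `"3:3"`, `"4:4"`,
#'   `"5:5"`, `"6:6"` (asymmetric pairs are applied in both directions) or
#'   `"any"` for all source/target lengths up to the table maximum.
#' @param prob Per-window substitution chance.
#' @param table An [build_isobaric_table()] result.
#' @param seed Optional integer seed.
#' @return Tibble with columns `original`, `altered`, `error_type`,
#'   `applicable` (had at least one substitutable window), `changed`,
#'   `levenshtein`.
#' @export
substitute_equal_mass <- function(seqs, length_pair = "2:2", prob = 0.25,
                                  table = build_isobaric_table(),
                                  seed = NULL) {
  specs <- length_pair_specs(length_pair, table$max_combo_len)
  type <- length_pair_type(length_pair)
  with_seed_if(seed, {
    altered <- character(length(seqs))
    applicable <- logical(length(seqs))
    for (s in seq_along(seqs)) {
      x <- strsplit(seqs[s], "", fixed = TRUE)[[1]]
      n <- length(x)
      out <- character(0)
      i <- 1L
      any_window <- FALSE
      while (i <= n) {
        substituted <- FALSE
        for (spec in specs) {
          if (i + spec$a - 1L > n) next
          w <- paste(x[i:(i + spec$a - 1L)], collapse = "")
          alts <- iso_alternatives(table, w, spec$bs)
          if (is.null(alts)) next
          any_window <- TRUE
          if (runif(1) < prob) {
            out <- c(out, sample_replacement(alts, w))
            i <- i + spec$a
            substituted <- TRUE
            break
          }
        }
        if (!substituted) {
          out <- c(out, x[i])
          i <- i + 1L
        }
      }
      altered[s] <- paste(out, collapse = "")
      applicable[s] <- any_window
    }
    errored_tibble(seqs, altered, type, applicable)
  })
}

#' Apply fragment inversions to peptides
#'
#' Each peptide is partitioned left to right into fragments of two or three
#' residues (fragment length drawn uniformly; a trailing single residue is
#' left unchanged). Each fragment is independently randomized with
#' probability `prob`; residue multiset and length are conserved.
#'
#' @param seqs Character vector of peptides.
#' @param prob Per-fragment randomization chance (default 0.05).
#' @param seed Optional integer seed.
#' @return Tibble as in [substitute_equal_mass()], `error_type "inversion"`.
#' @export
invert_fragments <- function(seqs, prob = 0.05, seed = NULL) {
  if (any(nchar(seqs) < 2)) {
    warning("peptides shorter than 2 residues returned unchanged")
  }
  with_seed_if(seed, {
    altered <- vapply(seqs, function(p) {
      n <- nchar(p)
      if (n < 2) return(p)
      x <- strsplit(p, "", fixed = TRUE)[[1]]
      out <- character(0)
      i <- 1L
      while (n - i + 1L >= 2L) {
        rest <- n - i + 1L
        flen <- if (rest == 2L) 2L else sample(2:3, 1)
        frag <- x[i:(i + flen - 1L)]
        if (runif(1) < prob) frag <- sample(frag)
        out <- c(out, frag)
        i <- i + flen
      }
      if (i <= n) out <- c(out, x[i:n])
      paste(out, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    errored_tibble(seqs, altered, "inversion", nchar(seqs) >= 2)
  })
}

# Codon lookup tables built once from the standard genetic code.
codon_tables <- function() {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  aa <- ALPHABET19
  counts <- lengths(by_aa[aa])
  m <- matrix(NA_character_, nrow = length(aa), ncol = max(counts),
              dimnames = list(aa, NULL))
  for (a in aa) m[a, seq_along(by_aa[[a]])] <- by_aa[[a]]
  list(codons = m, counts = counts, code = gc)
}

#' Apply codon-level mutations to peptides
#'
#' Each residue is reverse-translated into a codon chosen uniformly among its
#' standard-genetic-code synonyms; every nucleotide is then substituted by one
#' of the three other bases with probability `prob`, and the codons are
#' translated back. Codons that would translate to a stop have their mutated
#' positions re-drawn until a residue results, so output length equals input
#' length. Translated isoleucine is folded onto L, keeping the output in the
#' 19-letter alphabet.
#'
#' @param seqs Character vector of peptides.
#' @param prob Per-nucleotide substitution chance (default 0.01).
#' @param seed Optional integer seed.
#' @return Tibble as in [substitute_equal_mass()], `error_type "other"`.
#' @export
mutate_codons <- function(seqs, prob = 0.01, seed = NULL) {
  ct <- codon_tables()
  bases <- c("A", "C", "G", "T")
  with_seed_if(seed, {
    chars <- strsplit(seqs, "", fixed = TRUE)
    lens <- lengths(chars)
    flat <- unlist(chars, use.names = FALSE)
    n <- length(flat)
    if (n == 0) return(errored_tibble(seqs, seqs, "other", TRUE))
    row <- match(flat, rownames(ct$codons))
    if (anyNA(row)) stop("sequences must be over the 19-letter alphabet")
    pick <- 1L + floor(runif(n) * ct$counts[flat])
    codon <- ct$codons[cbind(row, pick)]
    nt <- cbind(substr(codon, 1, 1), substr(codon, 2, 2), substr(codon, 3, 3))
    mutate_mask <- matrix(runif(3L * n) < prob, ncol = 3)
    mutate_positions <- function(ntm, mask, rows) {
      for (j in 1:3) {
        hit <- rows[mask[rows, j]]
        if (length(hit) == 0) next
        cur <- match(ntm[hit, j], bases)
        ntm[hit, j] <- bases[((cur - 1L + sample.int(3, length(hit),
                                                     replace = TRUE)) %% 4L) + 1L]
      }
      ntm
    }
    nt <- mutate_positions(nt, mutate_mask, seq_len(n))
    aa_out <- unname(ct$code[paste0(nt[, 1], nt[, 2], nt[, 3])])
    guard <- 0L
    while (any(stop_rows <- which(aa_out == "*")) && length(stop_rows) > 0) {
      guard <- guard + 1L
      if (guard > 100L) stop("stop-codon resampling did not converge")
      ntr <- cbind(substr(codon[stop_rows], 1, 1),
                   substr(codon[stop_rows], 2, 2),
                   substr(codon[stop_rows], 3, 3))
      ntr <- mutate_positions(ntr, mutate_mask[stop_rows, , drop = FALSE],
                              seq_along(stop_rows))
      nt[stop_rows, ] <- ntr
      aa_out[stop_rows] <- unname(ct$code[paste0(ntr[, 1], ntr[, 2],
                                                 ntr[, 3])])
    }
    aa_out <- chartr("I", "L", aa_out)
    altered <- vapply(split(aa_out, rep(seq_along(seqs), lens)),
                      paste, character(1), collapse = "")
    errored_tibble(seqs, unname(altered), "other", TRUE)
  })
}

#' Levenshtein edit distance
#'
#' Standard unit-cost edit distance (insertions, deletions, substitutions),
#' computed elementwise over two equal-length vectors.
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Integer vector of distances.
#' @export
#' @examples
#' levenshtein("PEPTIDE", "PEPTLDE")
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  vapply(seq_len(n), function(i) as.integer(adist(a[i], b[i])), integer(1))
}

# Apply one named error type to a vector of peptides.
apply_error_type <- function(type, seqs, cfg, table) {
  pair <- c(sub_1_12 = "1:1/2", sub_2_2 = "2:2", sub_2_3 = "2:3",
            sub_3_3 = "3:3", sub_4_4 = "4:4", sub_5_5 = "5:5",
            sub_6_6 = "6:6")[type]
  if (!is.na(pair)) {
    substitute_equal_mass(seqs, pair, cfg$substitution_prob, table)
  } else if (type == "inversion") {
    suppressWarnings(invert_fragments(seqs, cfg$inversion_prob))
  } else {
    mutate_codons(seqs, cfg$mutation_prob)
  }
}

#' Build the combined error dataset
#'
#' For each input peptide one error type is drawn from
#' `cfg$combined_rates` and the corresponding generator applied with its
#' configured rate. The drawn type is recorded whenever it is applicable to
#' the peptide (at least one substitutable window for substitution types;
#' length >= 2 for inversions), even if the per-site chance produced no edit —
#' mirroring a mixture of per-type datasets. Inapplicable draws are redrawn up
#' to `max_retries` times, then fall back to the always-applicable `"other"`
#' type, so the output has exactly one record per input peptide.
#'
#' @param peptides Character vector of L-normalized peptides.
#' @param cfg An [error_sim_config()]; `cfg$seed` drives all randomness.
#' @param table Optional prebuilt [build_isobaric_table()] (built from `cfg`
#'   otherwise).
#' @param max_retries Redraw budget for inapplicable types (default 10).
#' @return Tibble with one row per input peptide: `original`, `altered`,
#'   `error_type`, `applicable`, `changed`, `levenshtein`.
#' @export
make_combined_dataset <- function(peptides, cfg = error_sim_config(),
                                  table = NULL, max_retries = 10) {
  stopifnot(length(peptides) > 0)
  if (is.null(table)) {
    table <- build_isobaric_table(cfg$max_combo_len, cfg$mass_tolerance)
  }
  rates <- cfg$combined_rates / sum(cfg$combined_rates)
  with_seed_if(cfg$seed, {
    n <- length(peptides)
    res <- vector("list", n)
    pending <- seq_len(n)
    types <- sample(names(rates), n, replace = TRUE, prob = rates)
    for (round in 0:max_retries) {
      if (length(pending) == 0) break
      if (round == max_retries) types[pending] <- "other"
      for (ty in unique(types[pending])) {
        idx <- pending[types[pending] == ty]
        out <- apply_error_type(ty, peptides[idx], cfg, table)
        ok <- out$applicable
        for (k in which(ok)) res[[idx[k]]] <- out[k, ]
        pending <- setdiff(pending, idx[ok])
      }
      if (length(pending) > 0 && round < max_retries) {
        types[pending] <- sample(names(rates), length(pending),
                                 replace = TRUE, prob = rates)
      }
    }
    dplyr::bind_rows(res)
  })
}

#' Build the panel of in silico error datasets
#'
#' Thirteen datasets over the same input peptides: the seven equal-mass
#' substitution length pairs at the configured window chance, pooled
#' any-length substitution at 25/50/100% window chance, fragment inversions
#' at 5%, codon mutations at the 5% calibration rate, and the combined
#' dataset at the per-type occurrence rates.
#'
#' @inheritParams make_combined_dataset
#' @return Named list of 13 tibbles, each with `length(peptides)` rows.
#' @export
make_error_datasets <- function(peptides, cfg = error_sim_config(),
                                table = NULL) {
  stopifnot(length(peptides) > 0)
  if (is.null(table)) {
    table <- build_isobaric_table(cfg$max_combo_len, cfg$mass_tolerance)
  }
  pairs <- c("1:1/2", "2:2", "2:3", "3:3", "4:4", "5:5", "6:6")
  out <- list()
  k <- 0L
  for (p in pairs) {
    k <- k + 1L
    out[[length_pair_type(p)]] <- substitute_equal_mass(
      peptides, p, cfg$substitution_prob, table, seed = child_seed(cfg$seed, k))
  }
  for (pr in c(0.25, 0.5, 1.0)) {
    k <- k + 1L
    out[[sprintf("sub_any_%d", round(100 * pr))]] <- substitute_equal_mass(
      peptides, "any", pr, table, seed = child_seed(cfg$seed, k))
  }
  out$inversion <- suppressWarnings(invert_fragments(
    peptides, cfg$inversion_prob, seed = child_seed(cfg$seed, k + 1L)))
  out$mutation <- mutate_codons(peptides, 0.05,
                                seed = child_seed(cfg$seed, k + 2L))
  cfg_comb <- cfg
  cfg_comb$seed <- child_seed(cfg$seed, k + 3L)
  out$combined <- make_combined_dataset(peptides, cfg_comb, table)
  out
}
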