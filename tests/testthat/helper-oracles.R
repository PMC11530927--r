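# Independent oracles used by the tests. These deliberately share no code
# with the package internals: plain dynamic programming, recursion, and
# direct set/sum arithmetic.

# Brute-force affine-gap Smith-Waterman raw score: a gap of length g costs
# gap_open + g * gap_extend.
oracle_local_score <- function(a, b, mat, gap_open, gap_extend) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      diag <- max(M[i, j], Ix[i, j], Iy[i, j]) + mat[x[i], y[j]]
      M[i + 1, j + 1] <- max(0, diag)
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                              Ix[i, j + 1] - gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                              Iy[i + 1, j] - gap_extend)
      best <- max(best, M[i + 1, j + 1], Ix[i + 1, j + 1], Iy[i + 1, j + 1])
    }
  }
  best
}

# Exhaustive recursive Levenshtein distance (memoized).
oracle_levenshtein <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    cost <- if (substr(a, i, i) == substr(b, j, j)) 0 else 1
    v <- min(rec(i - 1, j) + 1, rec(i, j - 1) + 1, rec(i - 1, j - 1) + cost)
    memo[[key]] <- v
    v
  }
  rec(nchar(a), nchar(b))
}

# --- LCA oracles: direct arithmetic over plain data frames ---------------

RANKS7 <- c("superkingdom", "phylum", "class", "order", "family", "genus",
            "species")

# Deepest common prefix of lineage id columns.
oracle_lca_con <- function(lin) {
  out <- rep(NA_integer_, 7)
  names(out) <- RANKS7
  for (k in seq_along(RANKS7)) {
    v <- lin[[paste0(RANKS7[k], "_taxid")]]
    if (length(v) == 0 || anyNA(v) || length(unique(v)) > 1) break
    out[k] <- v[1]
  }
  out
}

# Weighted: sort taxa by global frequency (ties by taxid), keep the minimal
# cumulative prefix >= cutoff, then conventional LCA of the kept lineages.
oracle_lca_w <- function(lin, weights, cutoff) {
  taxa <- unique(lin$taxid)
  w <- as.numeric(weights[as.character(taxa)])
  w[is.na(w)] <- 0
  if (all(w <= 0)) {
    w <- rep(1, length(w))
  } else {
    w[w <= 0] <- sum(w) * 1e-9 / length(w)
  }
  o <- order(-w, taxa)
  taxa <- taxa[o]; w <- w[o]
  cum <- cumsum(w) / sum(w)
  kept <- taxa[seq_len(min(which(cum >= cutoff - 1e-12)))]
  oracle_lca_con(lin[lin$taxid %in% kept, , drop = FALSE])
}

# Bitscore: per rank top-down, sum bitscores per taxon among hits compatible
# with what was already assigned; assign the taxon whose share exceeds the
# cutoff, else stop.
oracle_lca_bit <- function(hits, cutoff) {
  out <- rep(NA_integer_, 7)
  names(out) <- RANKS7
  keep <- rep(TRUE, nrow(hits))
  for (k in seq_along(RANKS7)) {
    col <- paste0(RANKS7[k], "_taxid")
    ok <- keep & !is.na(hits[[col]])
    if (!any(ok)) break
    sums <- c(by(hits$bitscore[ok], hits[[col]][ok], sum))
    share <- sums / sum(sums)
    if (max(share) <= cutoff) break
    win <- as.integer(names(share)[which.max(share)])
    out[k] <- win
    keep <- keep & !is.na(hits[[col]]) & hits[[col]] == win
  }
  out
}

# Extract the 7 assigned taxids from a package lineage row as a plain vector.
lineage_ids <- function(row) {
  v <- vapply(paste0(RANKS7, "_taxid"), function(c) row[[c]][1], integer(1))
  names(v) <- RANKS7
  v
}

# Analytic per-residue change probability of the codon-mutation process:
# enumerate mutation masks and alternative-base outcomes, conditioning
# stop codons on a redraw of the mutated positions (mask fixed), with
# translated I counted as L.
oracle_codon_change_prob <- function(p) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  aas <- setdiff(sort(unique(code)), "*")
  aas <- setdiff(aas, "I")
  change_given_codon <- function(codon, aa) {
    nt <- strsplit(codon, "")[[1]]
    total <- 0
    for (mask in 0:7) {
      bits <- as.logical(bitwAnd(mask, c(1L, 2L, 4L)))
      pm <- prod(ifelse(bits, p, 1 - p))
      alts <- lapply(1:3, function(i) if (bits[i]) setdiff(bases, nt[i])
                     else nt[i])
      combos <- expand.grid(alts[[1]], alts[[2]], alts[[3]],
                            stringsAsFactors = FALSE)
      outs <- code[apply(combos, 1, paste, collapse = "")]
      outs <- chartr("I", "L", outs)
      nonstop <- outs != "*"
      if (!any(nonstop)) next  # unreachable for the standard code
      total <- total + pm * mean(outs[nonstop] != aa)
    }
    total
  }
  probs <- vapply(aas, function(aa) {
    codons <- names(code)[code == aa]
    mean(vapply(codons, change_given_codon, numeric(1), aa = aa))
  }, numeric(1))
  mean(probs)  # uniform residue usage, matching the test input
}

# Random peptide generator over the 19-letter alphabet.
random_peptides <- function(n, len_range = c(7, 20)) {
  vapply(seq_len(n), function(i) {
    paste(sample(denovotax:::ALPHABET19,
                 sample(len_range[1]:len_range[2], 1), replace = TRUE),
          collapse = "")
  }, character(1))
}
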