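# Ungapped Karlin-Altschul statistics for converting raw local-alignment
# scores into bitscores. lambda is the positive root of
# sum_ij p_i p_j exp(lambda * s_ij) = 1; K is computed by the truncated
# Karlin-Altschul series over convolutions of the integer score distribution.
# These are ungapped statistics applied to gapped scores, i.e. a documented
# approximation; an external aligner's own bitscores take precedence when
# available.

# Fetch a named substitution matrix shipped with Biostrings.
get_substitution_matrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

# Integer score distribution induced by matrix + background frequencies.
score_distribution <- function(mat, bg) {
  letters <- names(bg)
  stopifnot(all(letters %in% rownames(mat)))
  s <- mat[letters, letters]
  q <- outer(bg, bg)
  agg <- tapply(as.vector(q), as.vector(s), sum)
  score <- as.integer(names(agg))
  prob <- as.numeric(agg) / sum(q)
  list(score = score, prob = prob)
}

vec_gcd <- function(x) Reduce(function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}, abs(x[x != 0]))

#' Karlin-Altschul parameters for a scoring system
#'
#' Solves for the ungapped `lambda` and `K` of a substitution matrix under
#' the given background residue frequencies. Used to express local alignment
#' raw scores in bits and to attach approximate E-values.
#'
#' @param matrix Matrix name shipped with Biostrings (`"PAM70"`, `"PAM30"`,
#'   `"BLOSUM62"`) or an actual substitution matrix.
#' @param bg Named background frequencies; defaults to uniform over the
#'   19-letter (I-free) alphabet used throughout the package.
#' @param n_iter Truncation depth of the K series (default 40).
#' @return List with `lambda` (per raw-score unit), `K`, and `H` (relative
#'   entropy, bits-free nat units per scaled score).
#' @export
karlin_params <- function(matrix = "PAM70",
                          bg = setNames(rep(1 / 19, 19), ALPHABET19),
                          n_iter = 40) {
  mat <- get_substitution_matrix(matrix)
  bg <- bg / sum(bg)
  sd <- score_distribution(mat, bg)
  if (sum(sd$score * sd$prob) >= 0) {
    stop("expected score must be negative for local alignment statistics")
  }
  if (max(sd$score) <= 0) stop("matrix has no positive scores")
  d <- vec_gcd(sd$score)
  s <- sd$score %/% d  # gcd-1 units
  p <- sd$prob
  f <- function(lam) sum(p * exp(lam * s)) - 1
  hi <- 0.5
  while (f(hi) < 0) hi <- hi * 2
  lambda_s <- uniroot(f, c(1e-9, hi), tol = 1e-12)$root
  H_s <- sum(p * s * exp(lambda_s * s))

  # Distribution of the k-step partial sums by iterated convolution.
  lo <- min(s); hiS <- max(s)
  base <- numeric(hiS - lo + 1)
  base[s - lo + 1] <- p
  pk <- base
  off <- lo          # pk[i] = P(S_k = off + i - 1)
  sigma <- 0
  for (k in seq_len(n_iter)) {
    if (k > 1) {
      pk <- as.numeric(stats::convolve(pk, rev(base), type = "open"))
      pk[pk < 0] <- 0
      off <- off + lo
    }
    vals <- off + seq_along(pk) - 1
    neg <- vals < 0
    sigma <- sigma + (sum(pk[neg] * exp(lambda_s * vals[neg])) +
                        sum(pk[!neg])) / k
  }
  K <- exp(-2 * sigma) / (H_s * (1 - exp(-lambda_s)))
  list(lambda = lambda_s / d, K = K, H = H_s / d)
}

# Cached per-matrix parameters (uniform 19-letter background).
karlin_cache <- new.env(parent = emptyenv())

karlin_for_matrix <- function(matrix) {
  stopifnot(is.character(matrix), length(matrix) == 1)
  if (is.null(karlin_cache[[matrix]])) {
    karlin_cache[[matrix]] <- karlin_params(matrix)
  }
  karlin_cache[[matrix]]
}

#' Convert raw alignment scores to bitscores
#'
#' @param raw_score Numeric vector of raw local alignment scores.
#' @param matrix Substitution matrix name (default `"PAM70"`).
#' @return Numeric vector of bitscores.
#' @export
bitscore_from_raw <- function(raw_score, matrix = "PAM70") {
  kp <- karlin_for_matrix(matrix)
  (kp$lambda * raw_score - log(kp$K)) / log(2)
}
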