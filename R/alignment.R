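#' @importFrom Biostrings pairwiseAlignment alignedPattern alignedSubject score
#'   AAStringSet readAAStringSet writeXStringSet width
#' @importFrom stats p.adjust pf pnorm lm anova setNames runif rnorm rbinom ecdf
#'   hclust as.dist cor.test
#' @importFrom utils read.delim write.table head
NULL

#' The 20 standard amino-acid one-letter codes
#'
#' Residues outside this alphabet (other than the ambiguity code `X`) are
#' masked to `X` before alignment and scored 0.
#' @export
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

#' Substitution matrix for clock-protein searches
#'
#' Returns the named substitution matrix with the ambiguity code `X` rescored
#' to 0 against every residue (including itself), so that masked residues are
#' alignment-neutral rather than penalised.
#'
#' @param name Matrix name; currently `"BLOSUM62"`.
#' @return A numeric substitution matrix.
#' @export
clock_submat <- function(name = "BLOSUM62") {
  if (!identical(name, "BLOSUM62")) {
    stop("unknown substitution matrix: ", name)
  }
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

#' Sanitise an amino-acid sequence
#'
#' Uppercases the sequence and maps nonstandard residues (B, Z, U, O, J, and
#' any other character outside the 20-letter alphabet, except gaps) to `X`.
#'
#' @param x Character vector of sequences.
#' @return Character vector of sanitised sequences.
#' @export
sanitize_aa <- function(x) {
  x <- toupper(x)
  vapply(x, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- !(chars %in% c(AA_STANDARD, "X", "-"))
    chars[bad] <- "X"
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment with affine gap penalties. A gap of length
#' k costs `gap_open + k * gap_extend` (the BLAST convention for
#' "open 11, extend 1"). Percent similarity is the BLAST-style "positives"
#' fraction: the proportion of alignment columns whose residue pair has a
#' positive substitution score (gap columns count toward the length but never
#' as positives).
#'
#' @param a,b Amino-acid sequences (single character strings).
#' @param matrix Substitution matrix name (see [clock_submat()]).
#' @param gap_open,gap_extend Affine gap parameters.
#' @return A list with elements `score`, `aln_length`, `percent_similarity`,
#'   and the aligned strings `aligned_a`, `aligned_b`. When no cell of the
#'   dynamic-programming matrix is positive the alignment is empty:
#'   `score = 0`, `aln_length = 0` and `percent_similarity` is `NA`.
#' @export
align_pair <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                       gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("align_pair: empty sequence")
  submat <- clock_submat(matrix)
  a <- sanitize_aa(a)
  b <- sanitize_aa(b)
  pa <- pairwiseAlignment(a, b, type = "local", substitutionMatrix = submat,
                          gapOpening = gap_open, gapExtension = gap_extend)
  sc <- score(pa)
  if (sc <= 0) {
    return(list(score = 0, aln_length = 0L, percent_similarity = NA_real_,
                aligned_a = "", aligned_b = ""))
  }
  pat <- as.character(alignedPattern(pa))
  sub <- as.character(alignedSubject(pa))
  list(score = sc,
       aln_length = nchar(pat),
       percent_similarity = percent_positives(pat, sub, submat),
       aligned_a = pat, aligned_b = sub)
}

# Positive-scoring column fraction of an aligned pair of equal-length strings.
percent_positives <- function(aligned_a, aligned_b, submat) {
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  both <- ca != "-" & cb != "-"
  pos <- sum(submat[cbind(ca[both], cb[both])] > 0)
  100 * pos / length(ca)
}

# Default Karlin-Altschul parameters for gapped BLOSUM62 (open 11, extend 1).
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Karlin-Altschul expectation value
#'
#' E = K * m * n * exp(-lambda * S) for a raw alignment score S, query length
#' m and total database residues n. Defaults are the conventional gapped
#' BLOSUM62 (11/1) constants; both are configurable.
#'
#' @param score Raw alignment score (>= 0).
#' @param query_len Query length in residues (m > 0).
#' @param db_residues Total residues in the searched database (n > 0).
#' @param lambda,K Karlin-Altschul parameters.
#' @return Expectation value (numeric, vectorised over `score`).
#' @export
estimate_evalue <- function(score, query_len, db_residues,
                            lambda = KA_LAMBDA, K = KA_K) {
  if (any(score < 0)) stop("estimate_evalue: negative score")
  if (query_len <= 0 || db_residues <= 0) {
    stop("estimate_evalue: query_len and db_residues must be positive")
  }
  K * query_len * db_residues * exp(-lambda * score)
}

#' Bit score from a raw alignment score
#'
#' @inheritParams estimate_evalue
#' @return Bit score, `(lambda * S - ln K) / ln 2`.
#' @export
bit_score <- function(score, lambda = KA_LAMBDA, K = KA_K) {
  (lambda * score - log(K)) / log(2)
}
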