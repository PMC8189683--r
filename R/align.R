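# Standard BLOSUM62 substitution matrix, hard-coded as data (half-bit
# units, NCBI values with ambiguity rows B/J/Z/X and stop *) so scores are
# reproducible with no external dependency.
BLOSUM62_ALPHABET <- "ARNDCQEGHILKMFPSTWYVBJZX*"
BLOSUM62 <- matrix(
  c( 4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,-2,-1,-1,-1,-4,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,-1,-2, 0,-1,-4,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3, 4,-3, 0,-1,-4,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3, 4,-3, 1,-1,-4,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-3,-1,-3,-1,-4,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2, 0,-2, 4,-1,-4,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2, 1,-3, 4,-1,-4,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,-1,-4,-2,-1,-4,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3, 0,-3, 0,-1,-4,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,-3, 3,-3,-1,-4,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,-4, 3,-3,-1,-4,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2, 0,-3, 1,-1,-4,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,-3, 2,-1,-1,-4,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-3, 0,-3,-1,-4,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,-2,-3,-1,-1,-4,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2, 0,-2, 0,-1,-4,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,-1,-1,-1,-1,-4,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,-4,-2,-2,-1,-4,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-3,-1,-2,-1,-4,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-3, 2,-2,-1,-4,
    -2,-1, 4, 4,-3, 0, 1,-1, 0,-3,-4, 0,-3,-3,-2, 0,-1,-4,-3,-3, 4,-3, 0,-1,-4,
    -1,-2,-3,-3,-1,-2,-3,-4,-3, 3, 3,-3, 2, 0,-3,-2,-1,-2,-1, 2,-3, 3,-3,-1,-4,
    -1, 0, 0, 1,-3, 4, 4,-2, 0,-3,-3, 1,-1,-3,-1, 0,-1,-2,-2,-2, 0,-3, 4,-1,-4,
    -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-4,
    -4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4, 1),
  nrow = 25, byrow = TRUE,
  dimnames = list(strsplit(BLOSUM62_ALPHABET, "")[[1L]],
                  strsplit(BLOSUM62_ALPHABET, "")[[1L]]))

# Karlin-Altschul parameters for gapped BLOSUM62 with affine gap cost
# 11 + k (opening 11, extension 1 per residue). Fixed constants so bit
# scores and E-values are reproducible across platforms.
KA_LAMBDA <- 0.267
KA_K <- 0.041
GAP_OPEN <- 11
GAP_EXTEND <- 1

aa_alphabet <- function() {
  # residues scorable under BLOSUM62, excluding the stop symbol
  setdiff(strsplit(BLOSUM62_ALPHABET, "")[[1L]], "*")
}

check_aa <- function(seq, arg = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(sprintf("%s must be a non-empty string", arg), call. = FALSE)
  seq <- toupper(seq)
  ch <- strsplit(seq, "")[[1L]]
  bad <- setdiff(unique(ch), aa_alphabet())
  if (length(bad))
    stop(sprintf("%s contains non-amino-acid character(s): %s",
                 arg, paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  seq
}

bits_from_raw <- function(raw) (KA_LAMBDA * raw - log(KA_K)) / log(2)

#' Score one pair of protein sequences
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps (opening
#' 11, extension 1 per gapped residue, i.e. a length-k gap costs `11 + k`).
#' The raw score is converted to a bit score with fixed Karlin-Altschul
#' constants (lambda = 0.267, K = 0.041, the published values for gapped
#' BLOSUM62 11/1), and the E-value follows the standard search-space
#' scaling:
#'
#' `E = length(seq_a) * db_residues * 2^(-bitscore)`
#'
#' Ambiguity codes (B, J, Z, X) are accepted and scored by their BLOSUM62
#' entries. The bit score is symmetric in its arguments; the E-value scales
#' with the first sequence's length.
#'
#' @param seq_a,seq_b Amino-acid sequences (non-empty strings).
#' @param db_residues Total residue count of the search space (positive).
#' @return Named list: `raw` (Smith-Waterman score), `bitscore`, `evalue`,
#'   and `pident` (percent identity over the local alignment's columns,
#'   0-100).
#' @export
builtin_pairwise <- function(seq_a, seq_b, db_residues) {
  seq_a <- check_aa(seq_a, "seq_a")
  seq_b <- check_aa(seq_b, "seq_b")
  stopifnot(is.numeric(db_residues), length(db_residues) == 1L, db_residues > 0)
  al <- .sw_align_cpp(seq_a, seq_b, BLOSUM62, BLOSUM62_ALPHABET,
                      GAP_OPEN, GAP_EXTEND)
  bits <- bits_from_raw(al$score)
  list(raw = al$score,
       bitscore = bits,
       evalue = nchar(seq_a) * db_residues * 2^(-bits),
       pident = if (al$columns > 0) 100 * al$matches / al$columns else 0)
}

# all-vs-all raw Smith-Waterman scores over (validated) sequences
sw_score_matrix <- function(seqs) {
  stopifnot(length(seqs) >= 1L)
  seqs <- vapply(seqs, check_aa, "", USE.NAMES = TRUE)
  m <- .sw_score_matrix_cpp(unname(seqs), BLOSUM62, BLOSUM62_ALPHABET,
                            GAP_OPEN, GAP_EXTEND)
  dimnames(m) <- list(names(seqs), names(seqs))
  m
}

# pairwise percent identity (local-alignment columns) for the guide tree
sw_pid_matrix <- function(seqs) {
  u <- length(seqs)
  m <- matrix(100, u, u, dimnames = list(names(seqs), names(seqs)))
  if (u == 1L) return(m)
  for (i in seq_len(u - 1L)) {
    for (j in (i + 1L):u) {
      p <- builtin_pairwise(seqs[[i]], seqs[[j]], db_residues = 1)$pident
      m[i, j] <- m[j, i] <- p
    }
  }
  m
}
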