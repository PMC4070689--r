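# Internal helpers shared across modules.

# IUPAC nucleotide ambiguity sets (DNA). Used by the primer matcher; any
# character outside this table counts as a mismatch at that position.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of nucleotide strings
#'
#' IUPAC ambiguity codes are complemented correctly (e.g. M -> K).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements (names preserved).
#' @examples
#' revcomp("AGAGTTTGATCMTGGCTCAG")
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# Uniform random DNA string of length `len`, using the current RNG stream.
random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Apply per-base substitution errors (rate per base) to a vector of reads.
# Substitutions are to a uniformly chosen different base.
add_substitution_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(r) {
    n <- nchar(r)
    k <- rbinom(1L, n, rate)
    if (k == 0L) return(r)
    pos <- sample.int(n, k)
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# stopifnot with a readable message
fail_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
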