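# k-mer encoding and genetic-code helpers shared across modules.
#
# Bases are coded A=0, C=1, G=2, T=3 (alphabetical, the Biostrings column
# order), and a k-mer index is the base-4 number with the first base most
# significant. All 4^k k-mers of a given k therefore sort lexicographically
# by index, which keeps oligonucleotideFrequency() output aligned with ours.

BASES <- c("A", "C", "G", "T")

#' Encode a DNA string as integer base codes
#'
#' @param x single character string over A/C/G/T/N (case-insensitive).
#' @return integer vector, A=0, C=1, G=2, T=3, NA for N or other letters.
#' @keywords internal
seq_to_int <- function(x) {
  stopifnot(length(x) == 1L)
  m <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], BASES)
  m - 1L
}

int_to_seq <- function(b) paste(BASES[b + 1L], collapse = "")

#' All k-mers of width k in index order
#' @keywords internal
kmer_strings <- function(k) {
  g <- expand.grid(rev(replicate(k, BASES, simplify = FALSE)),
                   stringsAsFactors = FALSE)
  do.call(paste0, rev(g))
}

#' Index (0-based) of a single k-mer string
#' @keywords internal
kmer_index <- function(s) {
  b <- seq_to_int(s)
  if (anyNA(b)) return(NA_integer_)
  as.integer(sum(b * 4^(rev(seq_along(b)) - 1L)))
}

#' Indices of all overlapping k-mers along an integer-coded sequence
#'
#' Linear scan; windows containing NA (ambiguous base) get index NA. When
#' `circular` the last k-1 windows wrap to the sequence start.
#' @keywords internal
window_kmer_indices <- function(b, k, circular = FALSE) {
  n <- length(b)
  if (circular) b <- c(b, b[seq_len(k - 1L)])
  nw <- if (circular) n else n - k + 1L
  if (nw < 1L) return(integer(0))
  idx <- numeric(nw)
  for (j in seq_len(k)) {
    idx <- idx + b[j:(j + nw - 1L)] * 4^(k - j)
  }
  as.integer(idx)
}

# Genetic code as a length-64 vector of single-letter amino acids ('*' stop),
# indexed by codon index + 1. Derived from the standard code in Biostrings.
aa_by_codon <- function() {
  codons <- kmer_strings(3L)
  unname(Biostrings::GENETIC_CODE[codons])
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate an in-frame DNA string (frame 0)
#' @keywords internal
translate_str <- function(x) {
  stopifnot(nchar(x) %% 3 == 0)
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     no.init.codon = TRUE))
}

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Coerce DNAStringSet or character vector to plain uppercase character.
as_seq_chr <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  toupper(unname(seqs))
}
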