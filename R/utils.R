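#' Convert between DNA and RNA alphabets
#'
#' Sequences are stored internally as DNA (U normalized to T on input); mature
#' miRNA sequences are reported as RNA at the output boundary only.
#'
#' @param x character vector of sequences.
#' @return character vector in the other alphabet, case preserved.
#' @export
as_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname as_rna
#' @export
as_dna <- function(x) chartr("Uu", "Tt", x)

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Vectorized Hamming distance between two equal-length sequence vectors.
hamming <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(integer(0))
  nc <- nchar(a)
  stopifnot(all(nc == nchar(b)))
  mapply(function(x, y) {
    sum(utf8ToInt(x) != utf8ToInt(y))
  }, a, b, USE.NAMES = FALSE)
}

# Validate a nucleotide string set; returns uppercase DNA (U -> T).
normalize_dna <- function(x, allow_n = TRUE) {
  x <- toupper(as_dna(x))
  ok <- grepl(if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$", x)
  list(seq = x, ok = ok)
}
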