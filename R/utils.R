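# Internal sequence helpers. All sequences are stored in the DNA alphabet
# (T, not U); RNA inputs are normalized on entry, RNA outputs on exit.

#' @useDynLib srnamir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Uppercases and converts U to T. Used on every external sequence input so
#' that mature catalogs written in RNA and genomes written in DNA compare
#' equal.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector in uppercase ACGTN alphabet.
#' @export
as_dna <- function(x) {
  chartr("uU", "tT", toupper(as.character(x)))
}

#' Convert a DNA-alphabet string to RNA
#' @param x character vector of nucleotide sequences.
#' @return character vector with T replaced by U.
#' @export
as_rna <- function(x) {
  chartr("tT", "uU", toupper(as.character(x)))
}

#' Reverse complement
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(as_dna(x))))
}

check_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", as_dna(x))
  if (any(bad)) {
    stop(sprintf("invalid %s alphabet (only ACGT/U/N allowed): %s",
                 what, substr(x[bad][1L], 1L, 40L)), call. = FALSE)
  }
  invisible(TRUE)
}

# Random DNA of the given lengths under a given RNG state.
random_dna <- function(n_lengths, alphabet = c("A", "C", "G", "T")) {
  bytes <- as.raw(utf8ToInt(paste(alphabet, collapse = "")))
  vapply(n_lengths, function(n) {
    rawToChar(sample(bytes, n, replace = TRUE))
  }, character(1))
}

# Longest run of a given letter in each sequence (0 if absent).
max_run <- function(x, letter = "A") {
  vapply(x, function(s) {
    r <- rle(strsplit(s, "")[[1]] == letter)
    runs <- r$lengths[r$values]
    if (length(runs)) max(runs) else 0L
  }, integer(1), USE.NAMES = FALSE)
}

# Fraction of a given letter per sequence.
letter_fraction <- function(x, letter = "A") {
  n <- nchar(x)
  cnt <- n - nchar(gsub(letter, "", x, fixed = TRUE))
  ifelse(n > 0L, cnt / n, 0)
}

# log(sum(exp(lx))) stable.
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}
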