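#' Reverse-complement a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequences
#'
#' Draws sequences i.i.d. uniform over A, C, G, T using the current RNG
#' state (set a seed beforehand for reproducibility).
#'
#' @param n number of sequences.
#' @param len length of each sequence in nt.
#' @return character vector of length `n`.
#' @export
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Substring of a (possibly circular) genome in 0-based half-open coordinates.
# Indices may run past the end only when circular.
genome_substr <- function(genome, start0, end0) {
  L <- nchar(genome$sequence)
  idx <- seq.int(start0, end0 - 1L)
  if (genome$circular) {
    idx <- idx %% L
  } else if (any(idx < 0L) || any(idx >= L)) {
    stop("coordinates [", start0, ",", end0, ") outside linear genome of length ", L)
  }
  paste(strsplit(genome$sequence, "", fixed = TRUE)[[1]][idx + 1L], collapse = "")
}

# Fast per-base access: genome as a character vector cache.
genome_chars <- function(genome) {
  strsplit(genome$sequence, "", fixed = TRUE)[[1]]
}
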