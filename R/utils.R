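# Small sequence helpers shared across modules. Sequences are plain
# upper-case character scalars in the A/C/G/T/N alphabet, major (J) strand
# orientation unless stated otherwise.

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' @param seq Character scalar over A/C/G/T/N (case-insensitive).
#' @return Character scalar, the reverse complement.
#' @examples
#' rev_comp("ATGCCC")
#' @export
rev_comp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

check_alphabet <- function(seq, what = "sequence") {
  if (grepl("[^ACGTN]", seq))
    stop(what, " contains characters outside the A/C/G/T/N alphabet",
         call. = FALSE)
  invisible(seq)
}

# split a string into single characters
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

#' The invertebrate mitochondrial genetic code (translation table 5)
#'
#' Codon-to-amino-acid map with the invertebrate mitochondrial reassignments
#' (TGA = Trp, ATA = Met, AGA/AGG = Ser); stops are TAA and TAG only.
#'
#' @param id Translation table identifier understood by
#'   [Biostrings::getGeneticCode()]; default `"5"`.
#' @return Named character vector of length 64 (names are codons, values
#'   one-letter amino-acid codes, `"*"` for stop).
#' @export
genetic_code <- function(id = "5") {
  Biostrings::getGeneticCode(as.character(id))
}

# cached table-5 lookups used in hot paths
.mc_cache <- new.env(parent = emptyenv())

code5 <- function() {
  if (is.null(.mc_cache$code5)) .mc_cache$code5 <- genetic_code("5")
  .mc_cache$code5
}

all_codons <- function() {
  if (is.null(.mc_cache$codons))
    .mc_cache$codons <- names(code5())
  .mc_cache$codons
}

sense_codons <- function() {
  gc <- code5()
  names(gc)[gc != "*"]
}

stop_codons <- function() {
  gc <- code5()
  names(gc)[gc == "*"]
}
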