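# Genetic-code utilities shared by all modules. The standard nuclear code is
# used throughout (dipteran nuclear genes).

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# named character vector: codon -> one-letter amino acid ("*" for stop)
.genetic_code <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
})

#' Translate a vector of codons to one-letter amino acids
#'
#' Codons containing characters other than A/C/G/T (N, gaps) translate to
#' `NA`; stop codons translate to `"*"`.
#'
#' @param codons character vector of 3-mers
#' @return character vector of amino acids
#' @export
translate_codons <- function(codons) {
  aa <- unname(.genetic_code[toupper(codons)])
  aa
}

is_stop_codon <- function(codons) toupper(codons) %in% STOP_CODONS

#' Split an in-frame nucleotide sequence into codons
#'
#' @param seq a single nucleotide string whose length is divisible by 3
#' @return character vector of codons
#' @export
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("sequence length (", n, ") is not divisible by 3")
  }
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(seq, starts, starts + 2L)
}

#' Reverse complement of nucleotide strings
#'
#' Keeps N and gap characters in place (complement of N is N, of '-' is '-').
#'
#' @param x character vector of nucleotide strings
#' @return character vector
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# validate that a string contains only A/C/G/T/N characters
.check_nucleotides <- function(seq, what = "sequence") {
  if (grepl("[^ACGTNacgtn]", seq)) {
    stop(what, " contains characters other than A, C, G, T, N")
  }
  invisible(TRUE)
}

# all 61 sense codons
.sense_codons <- local({
  all64 <- names(.genetic_code)
  all64[!all64 %in% STOP_CODONS]
})
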