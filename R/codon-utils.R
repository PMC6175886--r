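#' @importFrom Biostrings GENETIC_CODE DNAString DNAStringSet reverseComplement
NULL

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)

#' Translate a codon under the standard genetic code
#'
#' @param codon Character vector of 3-letter codons (A/C/G/T).
#' @return Character vector of one-letter amino acids, `"*"` for stop.
#' @export
translate_codon <- function(codon) {
  aa <- unname(Biostrings::GENETIC_CODE[toupper(codon)])
  if (anyNA(aa)) stop("invalid codon(s): ", paste(codon[is.na(aa)], collapse = ", "))
  aa
}

is_stop_codon <- function(codon) toupper(codon) %in% STOP_CODONS

#' Split a coding sequence into codons
#'
#' @param cds A single character string whose length is divisible by 3.
#' @return Character vector of codons.
#' @export
split_codons <- function(cds) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " not divisible by 3")
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a full CDS
#'
#' @param cds Character string, length divisible by 3.
#' @return Single amino-acid string (stops as `*`).
#' @export
translate_cds <- function(cds) {
  paste(translate_codon(split_codons(cds)), collapse = "")
}

# Reverse complement for plain character vectors.
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[toupper(b)]
}

# All single-base neighbours of a codon at one position.
codon_neighbours <- function(codon, pos) {
  ref <- substring(codon, pos, pos)
  alts <- setdiff(BASES, ref)
  vapply(alts, function(a) {
    out <- codon
    substring(out, pos, pos) <- a
    out
  }, character(1), USE.NAMES = FALSE)
}

# Random sense codons (no stops), vectorised.
sample_sense_codons <- function(n) {
  sample(SENSE_CODONS, n, replace = TRUE)
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}
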