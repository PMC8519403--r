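# Shared constants and small helpers.

# Canonical amino-acid alphabet, alphabetical (the package-wide letter order).
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA_LETTERS <- c("A", "C", "G", "T")

# IUPAC nucleotide ambiguity codes -> the set of bases each one matches.
# N is deliberately expanded to ACGT only: an N in a *subject* sequence is
# treated as unknown and matches nothing (handled at scan time).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (so 2.105 at 2 digits
#' becomes 2.11), matching how the family-survey percentage tables are
#' printed. Base R's `round()` rounds ties to even and would print 2.10.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits (default 2).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(25.263, 2.105, -2.105))
round_half_away <- function(x, digits = 2) {
  scale <- 10^digits
  # nudge by a hair to defeat binary representation of exact .5 ties
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Percentage of a count, printed-table style
#'
#' `100 * count / total`, rounded half-away-from-zero to two decimals --
#' e.g. 18 of 95 genes on one chromosome is 18.95.
#'
#' @param count numeric count(s).
#' @param total denominator.
#' @param digits decimal digits (default 2).
#' @return numeric percentage(s).
#' @export
proportion_percent <- function(count, total, digits = 2) {
  stopifnot(total > 0)
  round_half_away(100 * count / total, digits)
}

# Validate that a character scalar is a sequence over `alphabet`; returns the
# offending letters (empty if clean).
bad_letters <- function(seq, alphabet) {
  ch <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
  setdiff(ch, alphabet)
}

# Split a sequence string into a character vector of single letters.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Reverse complement of a DNA string (keeps N as N).
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Deterministic translation using the standard genetic code ("*" for stop).
translate_cds <- function(seq) {
  stopifnot(nchar(seq) %% 3 == 0)
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
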